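---
title: "Methods: quantifying polar bear aquatic behaviour from biologging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying polar bear aquatic behaviour from biologging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearswim)
```

# The problem

Adult female polar bears in the Barents Sea carry collars and archival tags
whose saltwater switches record when the animal is immersed, and in some
designs a pressure sensor records depth. Three tag families summarize that
signal in different ways before (or instead of) transmitting it, GPS fixes
are lost while the bear swims, and sea-ice conditions — the main driver of
swimming — must be attached from a gridded concentration product. `bearswim`
implements that whole chain: tag-firmware emulation, track processing,
covariate extraction and screening, behavioural summaries, and a binomial
generalized additive mixed model (GAMM) of swimming against sea-ice
concentration and season. A seeded synthetic-data generator stands in for
field data, so every stage can be verified quantitatively.

# Tag dialects

The three firmware dialects are implemented literally:

* **TDR (archival time-depth recorder).** Conductivity counts every 10 s;
  a sample is wet iff its reading is strictly below 100 counts (sea water
  reads well below 100, air well above). Wet samples are summed into clock-
  hour percent time in water (`classify_wet_tdr()`, `hourly_pct_wet_tdr()`).
  The strictness of the boundary (100 is dry) follows the stated rule
  "below 100"; it is isolated in one one-line function so the convention is
  easy to audit or change.
* **Telonics collar.** 1-s wet/dry; a swim starts after 5 consecutive wet
  seconds and ends at the first dry second; hourly percent time in water is
  the clipped swim seconds over 3600 (`detect_swims()` with
  `start_run = 5`, `hourly_pct_wet_telonics()`).
* **SMRU collar.** As above with a 12-s start rule; stores 4-h summaries
  (percent time in water, max depth, mean and max swim duration) and the
  individual swims, and transmits a random subset via Argos
  (`summarize_windows_smru()`, `argos_subsample()`).

Three conventions were genuinely open and are fixed as follows. The swim's
duration includes the qualifying start run (the 5/12-s requirement is a
detection criterion, not a trim), which makes total credited swim time equal
to the wet time of qualifying runs — the conservation property the tests
assert. A single dry second terminates an event and a later qualifying run
opens a new one; no merge gap is applied. Swims spanning a summary-window
boundary are clipped, each window being credited with its own seconds; this
is the only convention under which window percentages are provably at most
100. Missing sensor readings propagate as missing and are never imputed dry.

Because the 12-s rule admits a subset of the runs the 5-s rule admits, time
in water under the Telonics dialect is never below the SMRU dialect on the
same stream; and the hourly TDR percentage can differ from the true 1-s wet
fraction by at most the 10-s sampling quantization (about 10 s per wet/dry
transition per hour). Both properties are tested, the detector against an
independent second-by-second state-machine oracle on 10^4 random streams.

# Tracks and the 2-h time-in-water series

GPS fixes are nominally 2-hourly and are suppressed while the animal is
wet. Gaps strictly shorter than 48 h are filled by linear interpolation in
geographic degrees on the even 2-h UTC clock grid (anchoring to the clock
grid rather than the gap start is our choice; the alternative differs only
in phase). Gaps of 48 h or more are left empty. Linear interpolation in
degrees rather than along great circles is adequate at these latitudes and
gap scales (a 48-h gap at 2 km/h is under 100 km).

Each location gets the proportion of the 2-h window centred on it —
half-open, `[t - 1 h, t + 1 h)`, so boundary seconds are counted once —
spent in water: the mean of the two overlapped Telonics hourly values when
the collar reports them, otherwise the wet fraction of TDR samples in the
window, with Telonics taking precedence when both exist.

For long swims, the trip start and end are the last fix before and first
fix after the gap; distance is the great-circle (haversine, 6371-km sphere)
separation of those fixes, and swimming time within the trip is the measure
of the union of detected swim intervals clipped to it.

# Covariates and screening

Ice concentration is looked up as the containing 12.5-km grid cell on the
location's date — no bilinear interpolation, since concentration is an
areal product at that scale. Distance to land is the minimum over coastline
polygons of the closest-point-on-edge distance computed in a local
equirectangular frame centred on the point (about 1% accuracy at regional
scales), zero inside a polygon. The modelling subset keeps records with ice
strictly above 15%, at least 6.25 km from the large islands, at least 1 km
from small islands, and dated 1 March – 13 August inclusive; all four
bounds are tested at their boundaries and the filter is idempotent.

Since no NetCDF library is part of this package's dependency set, ice
fields serialize to a long-format CSV plus a JSON grid header; coastlines
are GeoJSON; everything else is CSV.

# Behavioural summaries

Daily percent time in water is wet time over recorded time within the UTC
day (the day-level definition feeding monthly means was unstated upstream;
this is the natural measure-theoretic choice). Monthly means per bear
require at least five days of data; months with fewer are omitted, not
zero-filled. Swim prevalence is the fraction of bear-days, bear-weeks or
bear-months containing any swimming, by calendar month, with each tag's own
dialect deciding "any swimming" (any wet TDR sample; any detected collar
swim). The reproductive contrast is an ordinary least-squares regression of
monthly means on a cubs-of-the-year indicator (females with yearlings and
without cubs pooled), fitted per calendar month. Space-use strategy is
classified with a reproducible rule replacing visual inspection: offshore
if any fix is farther than 50 km (configurable) from every island polygon,
unclassified if the track covers no complete June–September, local
otherwise — note that lowering the threshold can only move tracks toward
offshore, never the reverse. Daily maximum dive depths are summarized over
days with registered swims only, in 1-m bins.

# The swimming GAMM

The modelled responses for each screened 2-h record are the proportion of
the window in water (as binomial wet minutes out of 120) and indicators of
being wet at all, and at least 1, 10 and 60 minutes ("more than some
threshold" is implemented as `>=` at the threshold, `> 0` for "at all"; the
convention is isolated in `build_responses()`). Each is fitted as

`g(E[y]) = s(ice) + s(julian day)`, binomial logit,

with thin-plate splines (basis dimension 10 each), a per-bear random
intercept, and AR1 correlation within each bear's time-ordered window
series, via `mgcv::gamm()` (penalized quasi-likelihood through `nlme`),
which expresses exactly this error structure and is deterministic given the
data. The AR1 uses the absolute 2-h window index, so a gap of *g* windows
carries correlation `phi^g` — effectively a reset beyond a missing step or
two. Prediction curves are population-level (random intercept at zero) over
an ice grid of 15–100% at Julian days 61, 152 and 225 (1 March, 1 June,
13 August), with 95% intervals from the smooth standard errors on the link
scale; grid points outside the fitted covariate range are flagged as
extrapolation rather than refused.

A second engine (`engine = "gam"`) drops the AR1 term and fits the bear
intercept as a random-effect smooth by REML. It exists for simulation
studies: the null calibration of the ice smooth's significance test runs
500 replicate fits on independent null data, where the AR1 machinery is
both unnecessary (the null generator is iid) and far too slow.

# The synthetic-data generator

No generative model of polar bear swimming exists upstream, so the
generator is our own two-state semi-Markov construction, chosen for
testable parameter recovery. At the 2-h window scale the probability of
entering the water follows a logistic link: intercept, a slope per unit ice
fraction, a slope per Julian day, an additional April–July shift for
females with cubs-of-the-year, a normal per-bear intercept, and AR1 latent
noise. Given entry, bout durations are log-normal (and inter-bout spacing
within windows effectively exponential); dives beyond 1 m occur per bout
with fixed probability and exponential depth; depth is exactly zero outside
wet bouts. GPS fixes every 2 h are suppressed when the fix second is wet.
TDR streams encode wet as uniform 20–80 counts and dry as 150–250, so the
threshold-100 rule is exercised with margin on both sides.

Default parameters are the package's study conditions, chosen once to
reproduce the seasonal envelope reported for Barents Sea females: monthly
time in water near 2% in late winter rising to near 9% in mid-summer, most
swim days confined to the top metre with occasional dives beyond 10 m, and
daily swim prevalence above 75% in summer. Defaults: intercept −1.6, ice
slope −2.0 per unit fraction, season slope 0.008 d⁻¹, COY shift −1.2, bout
duration log-normal(log 900 s, 0.9), deep-bout probability 0.13 with 2-m
exponential scale, AR1 0.45 with sd 0.8, bear-intercept sd 0.9. The
simulated ice field is an inverse-logit of a seasonal cosine peaking in
mid-April and bottoming in mid-September plus a northward gradient and
smoothed noise — plausibility-level only, not ice physics; likewise the
generator makes no attempt at Argos location error or bear energetics.
What passing tests show is therefore that the pipeline's algorithms are
correct and that the model recovers known structure — not that real tags,
real tracks or real ice behave like the emulation.

The generator has two tiers sharing one link function: a window-level tier
returning 2-h time-in-water tables directly (cheap; used for cohort-scale
summaries and model fitting at tens of thousands of windows) and a full
tier materializing second-resolution streams (used wherever the firmware
emulators are under test).

# Verification design and problem sizes

The suite runs entirely on generated data. The sizes used are: 10^4 random
streams for the detector-oracle equivalence and the dialect-monotonicity
property; 300 streams for conservation and window bounds; 200 random gaps
for interpolation convexity; GAMM recovery on 20 bears × 5,000 windows
generated with a logit-linear ice effect of −3 per unit fraction — the fit
must give an effectively linear ice smooth (edf ≈ 1), recover the slope
within three standard errors, and produce monotone declining prediction
curves; 500 null replicates at n = 250 for the 5%-level calibration of the
smooth test; and a 60-bear April–July cohort for recovery of the
cubs-of-the-year suppression by the monthly OLS contrast. Recovery
simulations generate data satisfying the fitted model's assumptions (mild
latent noise): strong latent heterogeneity beyond the model would attenuate
marginal logistic slopes, which is a property of binary regression, not of
this implementation. The AR1 coefficient of a binomial PQL fit is a working
correlation and does not map one-to-one onto the generator's latent AR1
parameter; it is therefore checked comparatively (autocorrelated
generation must raise the fitted coefficient above matched independent
generation), not for unbiasedness.

# Known limitations

* Interpolation and distance computations use local flat-earth
  approximations appropriate for regional high-latitude work; they are not
  suitable for global-scale tracks.
* The PQL fit underlying `mgcv::gamm()` is approximate for binary
  responses; effective degrees of freedom and p-values are themselves
  approximations, which is why calibration is asserted in a band rather
  than at a point.
* The SMRU emulator treats sub-threshold wet runs as contributing nothing
  to stored percent time in water — the literal reading of the firmware
  description; if the real firmware counted them, SMRU summaries would be
  biased low relative to ours by the time in runs shorter than 12 s.
* Reproductive status is fixed per deployment (as determined at capture);
  cub loss during the season is not modelled.
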
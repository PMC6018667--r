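# bearswim

Quantifying the aquatic behaviour of polar bears (*Ursus maritimus*) from
biologging tags with saltwater switches and pressure sensors.

Collared female polar bears in regions like the Barents Sea carry three
kinds of instruments: archival time-depth recorders (10-s conductivity and
depth samples), Telonics collars (swims detected on-board after 5 s
continuously wet, ended by 1 dry second; hourly % time in water) and SMRU
collars (12-s start rule; 4-h summaries plus individual swims, partially
transmitted via Argos). GPS fixes are lost while the animal swims, and the
ecological driver of swimming — sea-ice concentration — lives in a gridded
raster. `bearswim` implements the full analysis chain for such data:

* **Tag emulation** — the three firmware dialects, applied to raw wet/dry +
  depth streams (`classify_wet_tdr()`, `detect_swims()`,
  `hourly_pct_wet_telonics()`, `summarize_windows_smru()`,
  `argos_subsample()`, `daily_max_depth()`).
* **Track processing** — linear gap interpolation on the 2-h clock grid
  with a 48-h cap, and the 2-h time-in-water value centred on each
  location with Telonics-over-TDR source precedence
  (`interpolate_track()`, `window_time_in_water()`).
* **Geospatial screening** — per-location ice concentration (containing
  12.5-km cell), distance to big/small island polygons, and the offshore
  filters: ice > 15%, ≥ 6.25 km from large islands, ≥ 1 km from small
  ones, 1 March – 13 August (`attach_covariates()`, `screen_offshore()`).
* **Behavioural summaries** — per-bear monthly means (≥ 5 days of data),
  swim prevalence by day/week/month, cubs-of-the-year contrasts,
  local/offshore strategy classification, long-swim metrics and dive-depth
  histograms (`monthly_means()`, `swim_prevalence()`,
  `reproductive_contrast()`, `classify_strategy()`,
  `summarize_long_swim()`, `depth_histogram()`).
* **The swimming model** — a binomial GAMM per response
  (proportion of a 2-h window in water as wet minutes / 120; wet at all /
  ≥ 1 min / ≥ 10 min / ≥ 60 min):
  `logit E[y] = s(ice) + s(julian day)` with a per-bear random intercept
  and AR1 within-bear residual correlation, fitted with `mgcv::gamm()`;
  population-level prediction curves over ice 15–100% at Julian days 61,
  152, 225 (`build_responses()`, `fit_swim_gamm()`,
  `predict_swim_curves()`).
* **Synthetic data** — a seeded generator for complete deployments
  (streams per tag dialect, tracks with wet-suppressed fixes, seasonal ice
  fields, coastlines, metadata) from a two-state semi-Markov behavioural
  model with a logistic swim-entry link, so every stage above is testable
  end to end (`behaviour_params()`, `simulate_windows()`,
  `simulate_deployment()`, `make_fixture_cohort()`, `run_pipeline()`).

## Worked example

Simulate a 20-bear season, summarize it, and fit the swimming model:

```r
library(bearswim)
library(dplyr)

p <- behaviour_params(seed = 1)           # study-condition defaults
w <- simulate_windows(p, n_bears = 20, start_date = "2015-03-01",
                      n_days = 153)       # 1 Mar - 31 Jul, 2-h windows

daily <- w |>
  group_by(bear_id, date) |>
  summarise(pct_tiw = 100 * mean(tiw), any_swim = any(any_swim),
            .groups = "drop")
bm <- monthly_means(daily)                # >= 5 days per bear-month
bm |> group_by(month) |> summarise(mean = mean(mean_pct_tiw), n = n())
#> # A tibble: 5 × 3
#>   month  mean     n
#>   <int> <dbl> <int>
#> 1     3  2.78    20
#> 2     4  3.09    20
#> 3     5  3.80    20
#> 4     6  5.25    20
#> 5     7  7.79    20
```

Monthly time in water climbs from about 2.8% in March to about 7.8% in
July for this seed — the winter-to-summer seasonal envelope the defaults
encode. For the model, a 21-day window table with a known ice effect
(logit slope −3 per unit ice fraction) fits in about a minute:

```r
p2 <- behaviour_params(ice_coeff = -3, seed = 1)
w2 <- simulate_windows(p2, n_bears = 20, start_date = "2015-03-01",
                       n_days = 21, ice_fun = function(doy, n) runif(n, 10, 100))
fit <- fit_swim_gamm(build_responses(w2), response = "ANY")
fit
#> <swim_gamm> response ANY (gamm engine), n = 5040 from 20 bears
#>   edf: s(ice_pct) = 1.00, s(julian_day) = 1.00
#>   AR1 phi = 0.031, random-intercept sd = 0.601

predict_swim_curves(fit, days = 61)[1:3, c("ice_pct", "julian_day", "p", "lo95", "hi95")]
#> # A tibble: 3 × 5
#>   ice_pct julian_day     p  lo95  hi95
#>     <dbl>      <dbl> <dbl> <dbl> <dbl>
#> 1      15         61 0.227 0.175 0.290
#> 2      16         61 0.223 0.171 0.284
#> 3      17         61 0.218 0.168 0.278
```

The fitted ice smooth is effectively linear (edf = 1.00) and negative —
bears swim less where ice concentration is high, after controlling for
season — with modest residual autocorrelation between consecutive 2-h
windows and a substantial between-bear intercept spread. The prediction
curves give the probability of swimming with 95% intervals over the
15–100% ice grid at 1 March (Julian day 61; days 152 and 225 are the other
reference days when the fitted season covers them).

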
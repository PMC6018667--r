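Package: bearswim
Title: Aquatic Behaviour of Polar Bears from Saltwater-Switch Biologging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying swimming and diving by polar bears carrying
    biologging tags with saltwater switches and pressure sensors. Emulates the
    on-board summarization algorithms of three tag families (archival
    time-depth recorders, Telonics collars, SMRU collars), processes GPS
    tracks with gap interpolation and a two-hour time-in-water precedence
    rule, extracts sea-ice concentration and distance-to-land covariates with
    offshore screening filters, computes behavioural summaries (monthly time
    in water, swim prevalence, reproductive-status contrasts, long-swim and
    dive-depth metrics), and fits binomial generalized additive mixed models
    relating swimming to sea-ice concentration and season with per-bear
    random intercepts and AR1 residual correlation. A seeded synthetic-data
    generator emulates complete deployments so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    mgcv,
    nlme,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
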
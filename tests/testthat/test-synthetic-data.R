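# The seeded deployment generator: determinism, degenerate behaviour
# regimes, link-function monotonicity, and on-disk round trips.

test_that("identical seeds give identical bundles, byte for byte", {
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  unlink(c(d1, d2), recursive = TRUE)
  make_fixture_cohort(2, seed = 11, dir = d1, duration_days = 2)
  make_fixture_cohort(2, seed = 11, dir = d2, duration_days = 2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 7)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "cohC")
  unlink(d3, recursive = TRUE)
  make_fixture_cohort(2, seed = 12, dir = d3, duration_days = 2)
  f <- file.path("streams", "B001_stream.csv")
  expect_false(identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d3, f)))))
})

test_that("degenerate swim probabilities give all-dry / all-wet streams", {
  p0 <- behaviour_params(base_swim_logit = -Inf, season_coeff = 0,
                         ice_coeff = 0, ar1_sd = 0, bear_intercept_sd = 0)
  d0 <- simulate_deployment(p0, "SMRU", 2)
  expect_true(all(d0$stream$conductivity == 0))
  expect_equal(nrow(d0$track), 2 * 12)            # no suppressed fixes
  expect_true(all(d0$stream$depth_m == 0))

  p1 <- behaviour_params(base_swim_logit = Inf, season_coeff = 0,
                         ice_coeff = 0, ar1_sd = 0, bear_intercept_sd = 0)
  d1 <- simulate_deployment(p1, "TELONICS", 2)
  # stream all wet; all fixes after the first (capture) are suppressed
  expect_true(all(d1$stream$conductivity == 1))
  expect_equal(nrow(d1$track), 1)
  expect_equal(d1$track$time[1], d1$start)
})

test_that("wet fraction decreases with ice concentration when ice_coeff < 0", {
  p <- behaviour_params(ice_coeff = -2.5, season_coeff = 0, seed = 5)
  low <- simulate_windows(p, n_bears = 10, "2015-06-01", 100,
                          ice_fun = function(doy, n) rep(20, n))
  high <- simulate_windows(p, n_bears = 10, "2015-06-01", 100,
                           ice_fun = function(doy, n) rep(90, n))
  expect_gt(mean(low$tiw), mean(high$tiw))
  expect_gt(mean(low$any_swim), mean(high$any_swim))
})

test_that("depth is exactly zero outside wet bouts", {
  d <- simulate_deployment(behaviour_params(seed = 9), "SMRU", 4)
  dry <- d$stream$conductivity == 0
  expect_true(all(d$stream$depth_m[dry] == 0))
  expect_true(all(d$stream$depth_m[!dry] > 0))
  # and on the 10-s TDR channel too
  dt <- simulate_deployment(behaviour_params(seed = 9), "TDR", 4)
  wet <- classify_wet_tdr(dt$stream$conductivity)
  expect_true(all(dt$stream$depth_m[!wet] == 0))
})

test_that("simulated ice fields have an April maximum and September minimum", {
  apr <- numeric(40); sep <- numeric(40)
  for (s in 1:40) {
    f <- simulate_ice_field(s, n_days = 365, extent_km = 100,
                            start_date = as.Date("2015-01-01"))
    apr[s] <- mean(f$conc[, , f$dates == as.Date("2015-04-15")])
    sep[s] <- mean(f$conc[, , f$dates == as.Date("2015-09-15")])
  }
  expect_gt(mean(apr), mean(sep))
  expect_gt(mean(apr > sep), 0.9)
  f1 <- simulate_ice_field(3, n_days = 1, extent_km = 50)
  expect_equal(dim(f1$conc)[3], 1)
  expect_true(all(f1$conc >= 0 & f1$conc <= 100))
  f2 <- simulate_ice_field(3, n_days = 1, extent_km = 50)
  expect_identical(f1, f2)
  expect_error(simulate_ice_field(1, 5, extent_km = -10), "positive")
})

test_that("a COY suppression effect shows up in April-July wet fractions", {
  p <- behaviour_params(coy_effect = -1.5, seed = 21)
  w <- simulate_windows(p, n_bears = 40, "2015-04-01", 60,
                        statuses = rep(c("COY", "NO_CUBS"), 20))
  g <- tapply(w$tiw, w$status, mean)
  expect_lt(g[["COY"]], g[["NO_CUBS"]])
})

test_that("one-deployment bundles round-trip through the readers", {
  dir <- file.path(tempdir(), "coh1")
  unlink(dir, recursive = TRUE)
  coh <- make_fixture_cohort(1, seed = 4, dir = dir, duration_days = 2)
  d <- coh$deployments[[1]]
  s <- read_stream_csv(file.path(dir, "streams", "B001_stream.csv"))
  expect_equal(nrow(s), nrow(d$stream))
  expect_equal(s$time, d$stream$time)
  expect_equal(s$conductivity, d$stream$conductivity, tolerance = 1e-3)
  tr <- read_track_csv(file.path(dir, "tracks", "B001_track.csv"))
  expect_equal(tr$lat, d$track$lat, tolerance = 1e-6)
  ice2 <- read_ice(file.path(dir, "ice"))
  expect_equal(ice2$conc, coh$ice$conc, tolerance = 1e-4)
  expect_equal(ice2$dates, coh$ice$dates)
  co2 <- read_coastline(file.path(dir, "coast.geojson"))
  expect_equal(co2$classes, coh$coast$classes)
  expect_equal(co2$polygons[[1]], coh$coast$polygons[[1]],
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(simulate_deployment(behaviour_params(), "SPOT", 2), "tag_type")
  expect_error(
    simulate_deployment(behaviour_params(), "TDR", 10, ice = coh$ice),
    "outside ice coverage")
})
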
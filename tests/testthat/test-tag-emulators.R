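# The three tag firmware dialects: wet/dry classification, swim detection,
# window summarization, transmission subsampling, daily depth maxima.

test_that("TDR wet/dry classification uses a strict 100-count threshold", {
  expect_equal(classify_wet_tdr(c(50, 100, 230)), c(TRUE, FALSE, FALSE))
  expect_true(is.na(classify_wet_tdr(NA_real_)))
  expect_equal(classify_wet_tdr(99.999), TRUE)
})

test_that("hourly TDR percentages count wet samples per clock hour", {
  t0 <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")
  mk <- function(n_wet, n = 360) {
    tibble::tibble(time = t0 + seq(0, by = 10, length.out = n),
                   conductivity = c(rep(50, n_wet), rep(200, n - n_wet)))
  }
  expect_equal(hourly_pct_wet_tdr(mk(0))$pct_wet, 0)
  expect_equal(hourly_pct_wet_tdr(mk(360))$pct_wet, 100)
  expect_equal(hourly_pct_wet_tdr(mk(90))$pct_wet, 25)
  # missing readings reduce the denominator rather than counting as dry
  s <- mk(90)
  s$conductivity[181:360] <- NA
  expect_equal(hourly_pct_wet_tdr(s)$pct_wet, 50)
})

test_that("irregular TDR sampling errors and names the first bad gap", {
  t0 <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")
  s <- tibble::tibble(time = t0 + c(0, 10, 20, 45), conductivity = 200)
  expect_error(hourly_pct_wet_tdr(s), "25 s gap after 2015-06-01 00:00:20")
})

test_that("swim detection applies the start-run rule and 1-s dry termination", {
  # alternating 4 s wet / 1 s dry: every run is below the 5-s start rule
  alt <- rep(c(rep(TRUE, 4), FALSE), 720)
  expect_equal(nrow(detect_swims(alt, 5)), 0)
  # a solid hour of wet is one swim
  one <- detect_swims(rep(TRUE, 3600), 5)
  expect_equal(one$duration_s, 3600L)
  # 10 s wet, 1 s dry, 20 s wet under both dialects
  seq3 <- c(rep(TRUE, 10), FALSE, rep(TRUE, 20))
  expect_equal(detect_swims(seq3, 5)$duration_s, c(10L, 20L))
  expect_equal(detect_swims(seq3, 12)$duration_s, 20L)
  expect_equal(nrow(detect_swims(logical(0), 5)), 0)
})

test_that("swim detection matches the brute-force oracle on random streams", {
  set.seed(101)
  for (i in 1:300) {
    wet <- random_wet_stream(sample(50:300, 1))
    for (run in c(5L, 12L)) {
      got <- detect_swims(wet, run,
                          t0 = as.POSIXct("2000-01-01", tz = "UTC"))
      want <- oracle_detect_swims(wet, run)
      expect_equal(as.numeric(got$start) - as.numeric(
        as.POSIXct("2000-01-01", tz = "UTC")) + 1, as.numeric(want$start_idx))
      expect_equal(got$duration_s, want$duration_s)
    }
  }
})

test_that("missing wet flags break runs without being counted as wet", {
  wet <- c(rep(TRUE, 6), NA, rep(TRUE, 6))
  got <- detect_swims(wet, 5)
  expect_equal(got$duration_s, c(6L, 6L))
  expect_equal(nrow(detect_swims(c(rep(TRUE, 4), NA, rep(TRUE, 4)), 5)), 0)
})

test_that("SMRU 4-h windows summarize clipped swims", {
  t0 <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")
  # two swims of 600 s and 1200 s wholly inside one window
  sw <- tibble::tibble(start = t0 + c(1000, 5000),
                       duration_s = c(600L, 1200L),
                       max_depth_m = c(0.5, 2))
  w <- summarize_windows_smru(sw)
  expect_equal(nrow(w), 1)
  expect_equal(w$pct_wet, 100 * 1800 / 14400)  # 12.5
  expect_equal(w$mean_dur_s, 900)
  expect_equal(w$max_dur_s, 1200)
  expect_equal(w$max_depth_m, 2)
  # a swim spanning a boundary: 100 s before, 200 s after
  sw2 <- tibble::tibble(start = t0 + 4 * 3600 - 100, duration_s = 300L,
                        max_depth_m = 1)
  w2 <- summarize_windows_smru(sw2)
  expect_equal(w2$pct_wet, 100 * c(100, 200) / 14400)
  expect_equal(w2$mean_dur_s, c(100, 200))
  # swim-free windows report 0% with empty depth/duration fields
  w3 <- summarize_windows_smru(sw, span = c(t0, t0 + 8 * 3600))
  expect_equal(w3$pct_wet[2], 0)
  expect_true(is.na(w3$max_depth_m[2]) && is.na(w3$mean_dur_s[2]))
})

test_that("in-window max depth uses the clipped seconds, not the whole swim", {
  t0 <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")
  # swim crosses the 4-h boundary; the deep excursion is entirely before it
  n <- 5 * 3600
  depth <- numeric(n)
  wet <- logical(n)
  a <- 4 * 3600 - 100
  wet[(a + 1):(a + 300)] <- TRUE
  depth[(a + 1):(a + 300)] <- 0.3
  depth[(a + 10):(a + 50)] <- 5          # deep part in the first window
  sw <- detect_swims(wet, 12, t0 = t0, depth = depth)
  w <- summarize_windows_smru(sw, depth = depth, t0 = t0)
  expect_equal(w$max_depth_m, c(5, 0.3))
})

test_that("Telonics hourly summaries credit clipped swim seconds per hour", {
  t0 <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")
  sw <- tibble::tibble(start = t0 + 3600 - 120, duration_s = 480L,
                       max_depth_m = NA_real_)
  h <- hourly_pct_wet_telonics(sw)
  expect_equal(h$pct_wet, 100 * c(120, 360) / 3600)
  expect_equal(h$window_h, c(1, 1))
})

test_that("Argos subsampling is seeded, unbiased and identity at fraction 1", {
  w <- tibble::tibble(window_start = 1:1000, pct_wet = runif(1000))
  expect_identical(argos_subsample(w, 1, 3), w)
  expect_identical(argos_subsample(w, 0.5, 3), argos_subsample(w, 0.5, 3))
  expect_error(argos_subsample(w, 0, 3), "fraction")
  kept <- vapply(1:200, function(s) nrow(argos_subsample(w, 0.5, s)),
                 numeric(1))
  # mean retained count within the 99% interval for a Binomial(1000, 0.5)
  # mean over 200 seeds: 500 +/- 2.576 * sqrt(250 / 200)
  expect_lt(abs(mean(kept) - 500), 2.576 * sqrt(250 / 200))
})

test_that("daily max depth covers only days with registered swims", {
  t0 <- as.POSIXct("2015-06-01 06:00:00", tz = "UTC")
  sw <- tibble::tibble(
    start = t0 + c(0, 3600, 7200, 86400 * 2),
    duration_s = c(60L, 60L, 60L, 60L),
    max_depth_m = c(0.2, 3.2, 1.1, 0.5))
  d <- daily_max_depth(sw)
  expect_equal(nrow(d), 2)                       # the dry day has no entry
  expect_equal(d$max_depth_m, c(3.2, 0.5))
  expect_error(daily_max_depth(tibble::tibble(
    start = t0, duration_s = 10L, max_depth_m = -1)), "negative")
  h <- depth_histogram(tibble::tibble(max_depth_m = 0.5))
  expect_equal(h$histogram$bin_lo, 0L)
})

test_that("hourly TDR percentage is within quantization error of the truth", {
  set.seed(7)
  for (i in 1:20) {
    wet1 <- random_wet_stream(3600)
    s <- tdr_stream_from_wet(wet1)
    got <- hourly_pct_wet_tdr(s)$pct_wet
    truth <- 100 * mean(wet1)
    n_trans <- sum(diff(wet1) != 0) + 1
    expect_lt(abs(got - truth), 100 * 10 * n_trans / 3600)
  }
})
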
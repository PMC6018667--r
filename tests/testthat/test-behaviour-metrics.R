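# Monthly means, swim prevalence, reproductive contrasts, strategy
# classification, long swims and dive-depth summaries.

test_that("monthly means enforce the five-day rule", {
  daily <- tibble::tibble(
    bear_id = "B1",
    date = as.Date("2015-06-01") + 0:3,          # 4 days only
    pct_tiw = c(10, 20, 30, 40))
  expect_equal(nrow(monthly_means(daily)), 0)
  daily5 <- tibble::tibble(bear_id = "B1",
                           date = as.Date("2015-06-01") + 0:4,
                           pct_tiw = rep(10, 5))
  expect_equal(monthly_means(daily5)$mean_pct_tiw, 10)
  daily6 <- tibble::tibble(bear_id = "B1",
                           date = as.Date("2015-06-01") + 0:5,
                           pct_tiw = c(0, 0, 0, 0, 0, 50))
  expect_equal(monthly_means(daily6)$mean_pct_tiw, 50 / 6, tolerance = 1e-9)
  # permutation invariance over days
  perm <- daily6[sample(6), ]
  expect_equal(monthly_means(perm)$mean_pct_tiw,
               monthly_means(daily6)$mean_pct_tiw)
  expect_error(monthly_means(dplyr::mutate(daily6, pct_tiw = 120)),
               "\\[0, 100\\]")
})

test_that("swim prevalence counts bears-with-swims per unit and month", {
  # 4 bears, one month: 3 swim at some point, 1 never does
  daily <- dplyr::bind_rows(lapply(1:4, function(i) tibble::tibble(
    bear_id = paste0("B", i), date = as.Date("2015-06-01") + 0:29,
    any_swim = if (i < 4) c(TRUE, rep(FALSE, 29)) else rep(FALSE, 30))))
  m <- swim_prevalence(daily, "month")
  expect_equal(m$prevalence, 0.75)
  expect_equal(m$n_units, 4L)
  all_swim <- dplyr::mutate(daily, any_swim = TRUE)
  for (p in c("day", "week", "month")) {
    expect_equal(swim_prevalence(all_swim, p)$prevalence, 1)
    expect_equal(swim_prevalence(
      dplyr::mutate(daily, any_swim = FALSE), p)$prevalence, 0)
  }
})

test_that("the reproductive contrast is the OLS group difference", {
  bm <- tibble::tibble(
    bear_id = paste0("B", 1:8), year_month = "2015-05", month = 5,
    mean_pct_tiw = c(10, 10, 10, 10, 10, 10, 10, 10),
    n_days = 10,
    reproductive_status = rep(c("COY", "NO_CUBS"), each = 4))
  r <- suppressWarnings(reproductive_contrast(bm, 5))  # zero-residual fit
  expect_equal(r$estimate, 0)
  shifted <- bm
  shifted$mean_pct_tiw[shifted$reproductive_status == "COY"] <- 5
  r2 <- suppressWarnings(reproductive_contrast(shifted, 5))
  expect_equal(r2$estimate, -5)
  expect_lt(r2$p_value, 1e-6)
  expect_error(reproductive_contrast(bm[bm$reproductive_status == "COY", ], 5),
               "month 5")
})

test_that("the contrast's false-positive rate is near nominal under the null", {
  set.seed(99)
  pvals <- replicate(400, {
    bm <- tibble::tibble(
      bear_id = paste0("B", 1:20), year_month = "2015-05", month = 5,
      mean_pct_tiw = pmax(0, rnorm(20, 8, 4)), n_days = 10,
      reproductive_status = rep(c("COY", "NO_CUBS"), 10))
    reproductive_contrast(bm, 5)$p_value
  })
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("strategy classification separates offshore, local, unclassified", {
  poly <- cbind(lon = c(14, 18, 18, 14), lat = c(77, 77, 79, 79))
  coast <- coastline(list(poly), "Island", "big")
  near <- tibble::tibble(
    time = as.POSIXct("2015-06-01", tz = "UTC") + (0:121) * 86400,
    lat = 79.02, lon = 16)                       # ~2 km off the north shore
  expect_equal(classify_strategy(near, coast), "LOCAL")
  off <- near
  off$lat[50] <- 81                              # one fix ~220 km offshore
  expect_equal(classify_strategy(off, coast), "OFFSHORE")
  spring_only <- near[1:30, ]                    # June only, no full summer
  expect_equal(classify_strategy(spring_only, coast), "UNCLASSIFIED")
  expect_error(classify_strategy(near[0, ], coast), "empty track")
  # monotone in the threshold: lowering it never turns OFFSHORE into LOCAL
  for (thr in c(100, 50, 20, 5)) {
    expect_equal(classify_strategy(off, coast, offshore_dist_km = thr),
                 "OFFSHORE")
  }
  expect_equal(classify_strategy(off, coast, offshore_dist_km = 500),
               "LOCAL")
})

test_that("long-swim summaries reproduce the trip arithmetic", {
  # a 28-h gap bridged by one 24-h continuous swim plus 2 h of shorter
  # swims: 26 h swimming of 28 h, max continuous 24 h
  t0 <- as.POSIXct("2015-05-18 00:00:00", tz = "UTC")
  trip <- tibble::tibble(start = t0, end = t0 + 28 * 3600,
                         start_lat = 79.6, start_lon = 11,
                         end_lat = 79.0, end_lon = 12.5)
  swims <- tibble::tibble(
    start = c(t0 + 600, t0 + 25 * 3600, t0 + 26.5 * 3600),
    duration_s = c(24L, 1L, 1L) * 3600L,
    max_depth_m = NA_real_)
  ls <- summarize_long_swim(trip, swims)
  expect_equal(ls$trip_hours, 28)
  expect_equal(ls$swim_hours, 26)
  expect_equal(ls$max_continuous_hours, 24)
  expect_equal(ls$distance_km,
               oracle_haversine_km(79.6, 11, 79.0, 12.5), tolerance = 1e-9)
  # no swims in the trip
  ls0 <- summarize_long_swim(trip, swims[0, ])
  expect_equal(ls0$swim_hours, 0)
  expect_equal(ls0$max_continuous_hours, 0)
  expect_error(summarize_long_swim(
    tibble::tibble(start = t0, end = t0, start_lat = 79, start_lon = 11,
                   end_lat = 79, end_lon = 11), swims), "after")
})

test_that("swim hours never exceed trip hours on random trips", {
  set.seed(12)
  t0 <- as.POSIXct("2015-06-01", tz = "UTC")
  for (i in 1:50) {
    trip <- tibble::tibble(start = t0, end = t0 + runif(1, 1, 40) * 3600,
                           start_lat = 79, start_lon = 11,
                           end_lat = 79.3, end_lon = 12)
    sw <- tibble::tibble(
      start = t0 + sort(runif(5, -5, 45)) * 3600,
      duration_s = as.integer(runif(5, 60, 6 * 3600)),
      max_depth_m = NA_real_)
    ls <- summarize_long_swim(trip, sw)
    expect_lte(ls$swim_hours, ls$trip_hours + 1e-9)
    expect_lte(ls$max_continuous_hours, ls$swim_hours + 1e-9)
  }
})

test_that("depth histograms use 1-m bins and report the surface share", {
  h <- depth_histogram(tibble::tibble(max_depth_m = c(0.5, 3.2, 13.9)))
  expect_equal(h$histogram$bin_lo, c(0L, 3L, 13L))
  expect_equal(h$histogram$n, c(1L, 1L, 1L))
  expect_equal(h$pct_surface_by_bear$pct_surface, 100 / 3, tolerance = 1e-9)
  all_surface <- depth_histogram(tibble::tibble(max_depth_m = rep(0.4, 10)))
  expect_equal(all_surface$pct_surface_mean, 100)
  empty <- depth_histogram(tibble::tibble(max_depth_m = numeric(0)))
  expect_equal(nrow(empty$histogram), 0)
  expect_error(depth_histogram(tibble::tibble(max_depth_m = -2)), "negative")
})
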
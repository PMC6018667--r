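# Track gap interpolation, the 2-h time-in-water precedence rule, and
# great-circle distances.

utc <- function(x) as.POSIXct(x, tz = "UTC")

test_that("gaps of 48 h or more are never interpolated; shorter gaps are", {
  tr <- tibble::tibble(
    time = utc(c("2015-06-01 00:00", "2015-06-03 00:00",   # exactly 48 h
                 "2015-06-05 02:00")),                     # 50 h
    lat = c(78, 78.5, 79), lon = c(15, 16, 17))
  out <- interpolate_track(tr)
  expect_equal(sum(out$interpolated), 0)
  tr2 <- tibble::tibble(
    time = utc(c("2015-06-01 00:00", "2015-06-02 23:59")), # just under 48 h
    lat = c(78, 78.5), lon = c(15, 16))
  out2 <- interpolate_track(tr2)
  expect_gt(sum(out2$interpolated), 0)
})

test_that("interpolated points are linear in time between the endpoints", {
  tr <- tibble::tibble(time = utc(c("2015-06-01 00:00", "2015-06-01 04:00")),
                       lat = c(78, 78), lon = c(15, 16))
  out <- interpolate_track(tr)
  mid <- out[out$interpolated, ]
  expect_equal(nrow(mid), 1)
  expect_equal(mid$time, utc("2015-06-01 02:00"))
  expect_equal(mid$lat, 78)
  expect_equal(mid$lon, 15.5)
})

test_that("interpolated coordinates stay inside the endpoint bounding box", {
  set.seed(31)
  for (i in 1:50) {
    t0 <- utc("2015-06-01 00:00") + runif(1, 0, 3600)
    gap <- runif(1, 2, 47.9) * 3600
    tr <- tibble::tibble(time = c(t0, t0 + gap),
                         lat = 70 + runif(2, 0, 10),
                         lon = runif(2, -20, 20))
    out <- interpolate_track(tr)
    ins <- out[out$interpolated, ]
    if (nrow(ins)) {
      expect_true(all(ins$lat >= min(tr$lat) & ins$lat <= max(tr$lat)))
      expect_true(all(ins$lon >= min(tr$lon) & ins$lon <= max(tr$lon)))
      expect_true(all(ins$time > tr$time[1] & ins$time < tr$time[2]))
    }
  }
  expect_error(interpolate_track(tibble::tibble(
    time = utc(c("2015-06-02 00:00", "2015-06-01 00:00")),
    lat = c(78, 78), lon = c(15, 16))), "increasing")
})

test_that("2-h time in water follows the Telonics-over-TDR precedence", {
  t <- utc("2015-06-01 12:00")
  tel <- tibble::tibble(
    window_start = utc(c("2015-06-01 11:00", "2015-06-01 12:00")),
    pct_wet = c(20, 40))
  expect_equal(window_time_in_water(t, telonics_hours = tel), 0.30)
  # TDR: 72 wet of 720 10-s samples in the window
  wet1 <- rep(FALSE, 7200); wet1[1:720] <- TRUE
  tdr <- tdr_stream_from_wet(wet1, t0 = utc("2015-06-01 11:00"))
  expect_equal(window_time_in_water(t, tdr_stream = tdr), 0.10)
  # both present and disagreeing: Telonics wins
  expect_equal(window_time_in_water(t, telonics_hours = tel,
                                    tdr_stream = tdr), 0.30)
  # neither covers the window
  expect_true(is.na(window_time_in_water(utc("2015-07-01 00:00"),
                                         telonics_hours = tel,
                                         tdr_stream = tdr)))
})

test_that("2-h time in water lies in [0, 1] whenever defined", {
  set.seed(55)
  wet1 <- random_wet_stream(86400)
  tdr <- tdr_stream_from_wet(wet1, t0 = utc("2015-06-01 00:00"))
  times <- utc("2015-06-01 01:00") + seq(0, 20 * 3600, by = 7200)
  v <- window_time_in_water(times, tdr_stream = tdr)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
})

test_that("great-circle distances match an independent haversine", {
  expect_equal(great_circle_km(78, 15, 78, 15), 0)
  expect_equal(great_circle_km(78, 15, 79, 15), 111.19, tolerance = 1e-3)
  set.seed(8)
  lat1 <- runif(50, -80, 80); lon1 <- runif(50, -179, 179)
  lat2 <- runif(50, -80, 80); lon2 <- runif(50, -179, 179)
  expect_equal(great_circle_km(lat1, lon1, lat2, lon2),
               oracle_haversine_km(lat1, lon1, lat2, lon2),
               tolerance = 1e-9)
  # symmetry, and agreement with geosphere on its 6371-km sphere
  expect_equal(great_circle_km(lat1, lon1, lat2, lon2),
               great_circle_km(lat2, lon2, lat1, lon1))
  expect_equal(great_circle_km(lat1[1], lon1[1], lat2[1], lon2[1]) * 1000,
               geosphere::distHaversine(c(lon1[1], lat1[1]),
                                        c(lon2[1], lat2[1]), r = 6371000),
               tolerance = 1e-6)
  expect_error(great_circle_km(95, 0, 0, 0), "invalid")
})

test_that("gap-bounded trips pick the fixes flanking each gap", {
  tr <- tibble::tibble(
    time = utc(c("2015-05-18 00:00", "2015-05-18 02:00",
                 "2015-05-19 06:00", "2015-05-19 08:00")),
    lat = c(79.5, 79.5, 79.0, 79.0), lon = c(10, 10.1, 12, 12.1))
  trips <- find_gap_trips(tr, min_gap_h = 4)
  expect_equal(nrow(trips), 1)
  expect_equal(trips$gap_h, 28)
  expect_equal(trips$start_lat, 79.5)
  expect_equal(trips$end_lat, 79.0)
})
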
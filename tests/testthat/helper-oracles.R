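# Independent oracles and small fixture builders used across tests.

# Brute-force swim detector: a literal second-by-second state machine
# (no run-length encoding), kept deliberately independent of the package's
# implementation. Returns 1-based start index and duration of each event.
oracle_detect_swims <- function(wet, start_run) {
  starts <- integer(0); durs <- integer(0)
  run <- 0L
  for (i in seq_along(wet)) {
    w <- !is.na(wet[i]) && wet[i]
    if (w) {
      run <- run + 1L
    } else {
      if (run >= start_run) {
        starts <- c(starts, i - run)
        durs <- c(durs, run)
      }
      run <- 0L
    }
  }
  if (run >= start_run) {
    starts <- c(starts, length(wet) - run + 1L)
    durs <- c(durs, run)
  }
  data.frame(start_idx = starts, duration_s = durs)
}

# Random 1-s wet/dry sequences with run structure (alternating geometric
# runs), covering short runs around the 5/12-s thresholds.
random_wet_stream <- function(len, p_wet_run = NULL) {
  mean_wet <- sample(c(2, 4, 6, 11, 13, 30), 1)
  mean_dry <- sample(c(1, 2, 5, 20), 1)
  out <- logical(0)
  state <- runif(1) < 0.5
  while (length(out) < len) {
    r <- 1L + rpois(1, if (state) mean_wet else mean_dry)
    out <- c(out, rep(state, r))
    state <- !state
  }
  out[seq_len(len)]
}

# Total time in water credited by a detection dialect (sum of event
# durations).
dialect_tiw <- function(wet, start_run) {
  sum(detect_swims(wet, start_run)$duration_s)
}

# Straight haversine on the 6371-km sphere, written independently of the
# package (different formulation: central angle via atan2).
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad; dlmb <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlmb / 2)^2
  6371 * 2 * atan2(sqrt(a), sqrt(1 - a))
}

# TDR stream builder: 10-s samples from a 1-s wet vector, with wet/dry
# conductivity encodings well away from the 100-count threshold.
tdr_stream_from_wet <- function(wet1s, t0 = as.POSIXct("2015-06-01",
                                                       tz = "UTC")) {
  idx <- seq(1L, length(wet1s), by = 10L)
  tibble::tibble(
    time = t0 + idx - 1L,
    conductivity = ifelse(wet1s[idx], 50, 200),
    depth_m = 0)
}

# Fitted log-odds slope of the ice smooth between two concentrations,
# with its standard error, via the linear-predictor matrix.
fitted_ice_slope <- function(fit, ice_a = 20, ice_b = 90, day = 152) {
  nd <- data.frame(ice_pct = c(ice_a, ice_b), julian_day = day, step = 0L)
  if (fit$engine == "gam") {
    nd$bear_id <- fit$gam$model$bear_id[1]
  }
  Xp <- mgcv::predict.gam(fit$gam, newdata = nd, type = "lpmatrix",
                          newdata.guaranteed = TRUE)
  dr <- (Xp[2, ] - Xp[1, ]) / ((ice_b - ice_a) / 100)  # per unit ice fraction
  est <- sum(dr * coef(fit$gam))
  se <- sqrt(drop(t(dr) %*% fit$gam$Vp %*% dr))
  c(slope = est, se = se)
}
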
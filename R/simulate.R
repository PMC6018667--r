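#' Behavioural parameters for the deployment simulator
#'
#' Collects the generative parameters of the synthetic aquatic-behaviour
#' model. Swimming is a two-state (dry/wet) semi-Markov process driven at
#' the 2-hour window scale by a logistic link
#' \deqn{\mathrm{logit}\, p = \beta_0 + \beta_{ice}\,c + \beta_{day}\,d + b_i + \epsilon_t,}
#' where \eqn{c} is sea-ice concentration as a fraction in \[0, 1\], \eqn{d}
#' is Julian day, \eqn{b_i} a per-bear normal intercept and \eqn{\epsilon_t}
#' AR1 latent noise; \eqn{p} is the probability that the bear enters the
#' water at all during the window. Given entry, swim bouts have log-normal
#' durations; dives within bouts reach an exponentially distributed maximum
#' depth with probability `deep_dive_prob`, otherwise the bear stays at the
#' surface (< 1 m).
#'
#' Defaults are chosen so that a simulated cohort shows the seasonal range
#' observed in Barents Sea females — monthly time in water of roughly 2% in
#' late winter rising to roughly 9% in mid-summer, most swim days confined
#' to the top metre, and occasional dives beyond 10 m.
#'
#' @param base_swim_logit intercept of the swim-entry logit.
#' @param ice_coeff logit slope per unit ice fraction (ice at 100% adds
#'   `ice_coeff` to the logit); negative means less swimming in heavy ice.
#' @param season_coeff logit slope per Julian day.
#' @param coy_effect additional logit shift applied to females with
#'   cubs-of-the-year during April--July (negative = suppression).
#' @param bout_duration_mean_log,bout_duration_sd_log log-scale mean and sd
#'   of swim-bout durations in seconds.
#' @param dive_depth_scale scale (metres) of the exponential depth of
#'   non-surface dives (added to a 1-m threshold).
#' @param deep_dive_prob probability that a bout contains a dive beyond 1 m.
#' @param ar1_rho AR1 coefficient of the latent logit noise, in (-1, 1).
#' @param ar1_sd marginal sd of the latent logit noise.
#' @param bear_intercept_sd sd of the per-bear random intercept (logit).
#' @param seed integer seed used by the simulators.
#'
#' @return A list of class `behaviour_params`.
#' @export
behaviour_params <- function(base_swim_logit = -1.6,
                             ice_coeff = -2.0,
                             season_coeff = 0.008,
                             coy_effect = -1.2,
                             bout_duration_mean_log = log(900),
                             bout_duration_sd_log = 0.9,
                             dive_depth_scale = 2.0,
                             deep_dive_prob = 0.13,
                             ar1_rho = 0.45,
                             ar1_sd = 0.8,
                             bear_intercept_sd = 0.9,
                             seed = 1L) {
  if (!(ar1_rho > -1 && ar1_rho < 1)) stop("ar1_rho must lie in (-1, 1)")
  if (deep_dive_prob < 0 || deep_dive_prob > 1) {
    stop("deep_dive_prob must lie in [0, 1]")
  }
  stopifnot_scalar_number(bout_duration_sd_log, "bout_duration_sd_log",
                          positive = TRUE)
  stopifnot_scalar_number(dive_depth_scale, "dive_depth_scale", positive = TRUE)
  structure(
    list(base_swim_logit = base_swim_logit, ice_coeff = ice_coeff,
         season_coeff = season_coeff, coy_effect = coy_effect,
         bout_duration_mean_log = bout_duration_mean_log,
         bout_duration_sd_log = bout_duration_sd_log,
         dive_depth_scale = dive_depth_scale,
         deep_dive_prob = deep_dive_prob,
         ar1_rho = ar1_rho, ar1_sd = ar1_sd,
         bear_intercept_sd = bear_intercept_sd,
         seed = as.integer(seed)),
    class = "behaviour_params"
  )
}

WINDOW_S <- 7200L  # 2-h behaviour window, matching the GPS fix schedule

# Seasonal default ice trajectory (percent) at day-of-year doy with additive
# logit-scale noise; peaks mid-April, minimal mid-September.
seasonal_ice_pct <- function(doy, noise = 0) {
  100 * stats::plogis(1.8 * cos(2 * pi * (doy - 105) / 365.25) + noise)
}

# AR1 series with marginal sd `sd` and coefficient `rho`.
ar1_series <- function(n, rho, sd) {
  if (n == 0L) return(numeric(0))
  e <- stats::rnorm(n, 0, sd * sqrt(max(1e-12, 1 - rho^2)))
  as.numeric(stats::filter(e, rho, method = "recursive", init = stats::rnorm(1, 0, sd)))
}

# Window-level swim draw shared by both simulator tiers. Returns per-window
# any-swim indicator and bout durations (seconds, total capped at the
# window). `eta` is the linear predictor including all noise.
draw_window_bouts <- function(eta, params) {
  n <- length(eta)
  p <- stats::plogis(eta)
  any_swim <- stats::runif(n) < p
  bouts <- vector("list", n)
  idx <- which(any_swim)
  if (length(idx)) {
    n_bouts <- 1L + stats::rpois(length(idx), 0.3)
    for (j in seq_along(idx)) {
      if (is.infinite(eta[idx[j]])) {
        # swim probability exactly 1: the bear never leaves the water
        bouts[[idx[j]]] <- WINDOW_S
        next
      }
      d <- stats::rlnorm(n_bouts[j], params$bout_duration_mean_log,
                         params$bout_duration_sd_log)
      d <- pmax(1, round(d))
      # clip the bout set so total wet time (plus separating dry seconds)
      # fits in the window
      cum <- cumsum(d + 1L)
      d <- d[cum <= WINDOW_S]
      if (length(d) == 0L) d <- min(WINDOW_S - 1L, max(1, round(
        stats::rlnorm(1, params$bout_duration_mean_log,
                      params$bout_duration_sd_log))))
      bouts[[idx[j]]] <- d
    }
  }
  any_swim <- lengths(bouts) > 0L
  list(any_swim = any_swim, bouts = bouts, p = p)
}

#' Simulate 2-hour swimming windows for a cohort
#'
#' The light tier of the deployment simulator: draws, for each bear, the
#' 2-hour window series of time in water directly from the behavioural model
#' of [behaviour_params()], without materializing second-resolution sensor
#' streams. Suitable for cohort-scale work (monthly summaries, prevalence,
#' model fitting) where only window/daily aggregates matter.
#'
#' @param params a [behaviour_params].
#' @param n_bears number of bears.
#' @param start_date first day (Date or coercible).
#' @param n_days days per bear.
#' @param statuses reproductive status per bear (`"NO_CUBS"`, `"COY"`,
#'   `"YEARLING"`); default all `"NO_CUBS"`; recycled.
#' @param ice_fun optional `function(doy, n)` returning ice percent for a
#'   bear's windows; default is a seasonal trajectory with per-bear AR1
#'   noise.
#' @param seed overrides `params$seed`.
#'
#' @return A tibble with one row per bear-window: `bear_id`, `status`,
#'   `time` (window start, UTC), `date`, `julian_day`, `step` (window index),
#'   `ice_pct`, `p_true` (generator swim-entry probability), `any_swim`,
#'   `wet_s`, `tiw` (proportion in \[0, 1\]).
#' @export
simulate_windows <- function(params, n_bears, start_date, n_days,
                             statuses = "NO_CUBS", ice_fun = NULL,
                             seed = params$seed) {
  stopifnot(inherits(params, "behaviour_params"))
  stopifnot_scalar_number(n_bears, "n_bears", positive = TRUE)
  stopifnot_scalar_number(n_days, "n_days", positive = TRUE)
  statuses <- rep_len(statuses, n_bears)
  start <- as_utc(paste(as.Date(start_date), "00:00:00"))
  n_win <- as.integer(n_days) * 12L
  times <- start + WINDOW_S * (seq_len(n_win) - 1L)
  doy <- julian_day(times)
  month <- as.integer(format(times, "%m"))

  with_seed(child_seed(seed, "windows"), {
    b <- stats::rnorm(n_bears, 0, params$bear_intercept_sd)
    out <- vector("list", n_bears)
    for (i in seq_len(n_bears)) {
      ice <- if (is.null(ice_fun)) {
        seasonal_ice_pct(doy, ar1_series(n_win, 0.97, 0.8))
      } else {
        ice_fun(doy, n_win)
      }
      coy <- if (statuses[i] == "COY") {
        params$coy_effect * (month >= 4 & month <= 7)
      } else 0
      eta <- params$base_swim_logit + params$ice_coeff * ice / 100 +
        params$season_coeff * doy + coy + b[i] +
        ar1_series(n_win, params$ar1_rho, params$ar1_sd)
      dw <- draw_window_bouts(eta, params)
      wet_s <- vapply(dw$bouts, function(d) sum(d %||% 0), numeric(1))
      out[[i]] <- tibble::tibble(
        bear_id = sprintf("B%03d", i), status = statuses[i],
        time = times, date = utc_day(times), julian_day = doy,
        step = seq_len(n_win), ice_pct = ice, p_true = dw$p,
        any_swim = dw$any_swim, wet_s = wet_s, tiw = wet_s / WINDOW_S)
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate one tagged deployment
#'
#' The full tier of the simulator: generates a complete deployment — a
#' second-resolution wet/dry (and depth) sensor stream, a GPS track with
#' fixes suppressed while the bear is wet (collar antennas do not transmit
#' under water), and metadata — from the behavioural model of
#' [behaviour_params()]. The stream is encoded per tag dialect:
#'
#' * `"TDR"`: conductivity counts every 10 s (wet uniform in \[20, 80\],
#'   dry uniform in \[150, 250\], so the threshold-100 rule is exercised
#'   with margin) plus depth;
#' * `"TELONICS"`: wet flag (0/1) at 1-s resolution, no depth channel;
#' * `"SMRU"`: wet flag at 1-s resolution plus depth.
#'
#' @param params a [behaviour_params].
#' @param tag_type `"TDR"`, `"TELONICS"` or `"SMRU"`.
#' @param duration_days deployment length in days (>= 1).
#' @param ice optional [ice_field]; when supplied, must cover the deployment
#'   dates, and the bear's local cell concentration drives the swim logit.
#'   When `NULL`, a seasonal ice trajectory is used.
#' @param coast optional [coastline] used to place the start position.
#' @param bear_id,start,reproductive_status deployment metadata.
#' @param offshore if `TRUE`, the track makes a mid-deployment offshore
#'   excursion (for exercising strategy classification).
#' @param seed overrides `params$seed`.
#'
#' @return A list of class `deployment`: metadata fields, `stream` (tibble
#'   `time`, `conductivity`, `depth_m`), `track` (tibble `time`, `lat`,
#'   `lon`, `quality`), `bouts` (tibble of true swim bouts: `start_s`,
#'   `duration_s`, `max_depth_m`), and `windows` (the underlying 2-h table).
#' @export
simulate_deployment <- function(params, tag_type, duration_days,
                                ice = NULL, coast = NULL,
                                bear_id = "B001",
                                start = "2015-04-01 00:00:00",
                                reproductive_status = "NO_CUBS",
                                offshore = FALSE,
                                seed = params$seed) {
  stopifnot(inherits(params, "behaviour_params"))
  if (!tag_type %in% c("TDR", "TELONICS", "SMRU")) {
    stop("unknown tag_type: ", tag_type)
  }
  stopifnot_scalar_number(duration_days, "duration_days", positive = TRUE)
  start <- as_utc(start)
  n_win <- as.integer(duration_days) * 12L
  times <- start + WINDOW_S * (seq_len(n_win) - 1L)
  dates <- utc_day(times)
  doy <- julian_day(times)
  month <- as.integer(format(times, "%m"))
  if (!is.null(ice)) {
    if (min(dates) < min(ice$dates) || max(dates) > max(ice$dates)) {
      stop("deployment dates outside ice coverage")
    }
  }

  with_seed(child_seed(seed, paste0("deploy-", bear_id, "-", tag_type)), {
    b <- stats::rnorm(1, 0, params$bear_intercept_sd)
    eps <- ar1_series(n_win, params$ar1_rho, params$ar1_sd)
    # start position: just off the first big-island coast if provided
    if (!is.null(coast)) {
      big <- which(coast$classes == "big")[1]
      p0 <- colMeans(coast$polygons[[if (is.na(big)) 1 else big]])
      lat <- p0[2] + stats::runif(1, 0.5, 0.9); lon <- p0[1] + stats::runif(1, -0.5, 0.5)
    } else {
      lat <- 78 + stats::runif(1, -0.5, 0.5); lon <- 16 + stats::runif(1, -1, 1)
    }
    home <- c(lat, lon)
    excursion <- offshore && n_win >= 24L
    exc_win <- if (excursion) seq(floor(n_win / 3), floor(2 * n_win / 3)) else integer(0)

    ice_pct <- numeric(n_win)
    eta <- numeric(n_win)
    coy <- if (reproductive_status == "COY") {
      params$coy_effect * (month >= 4 & month <= 7)
    } else rep(0, n_win)
    lat_t <- numeric(n_win); lon_t <- numeric(n_win)
    ice_noise <- ar1_series(n_win, 0.97, 0.8)
    bouts_all <- list()
    wet_win <- logical(n_win)

    for (w in seq_len(n_win)) {
      lat_t[w] <- lat; lon_t[w] <- lon
      ice_here <- if (!is.null(ice)) {
        v <- extract_ice(lat, lon, dates[w], ice)
        if (is.na(v)) seasonal_ice_pct(doy[w], ice_noise[w]) else v
      } else {
        seasonal_ice_pct(doy[w], ice_noise[w])
      }
      ice_pct[w] <- ice_here
      eta[w] <- params$base_swim_logit + params$ice_coeff * ice_here / 100 +
        params$season_coeff * doy[w] + coy[w] + b + eps[w]
      # random-walk step toward home (local bears) or offshore waypoint
      target <- if (w %in% exc_win) home + c(2.2, 0) else home
      lat <- lat + 0.03 * (target[1] - lat) + stats::rnorm(1, 0, 0.015)
      lon <- lon + 0.03 * (target[2] - lon) + stats::rnorm(1, 0, 0.045)
    }

    dw <- draw_window_bouts(eta, params)
    # place bouts inside their windows with >= 1 s dry separation
    for (w in which(dw$any_swim)) {
      d <- dw$bouts[[w]]
      slack <- WINDOW_S - sum(d) - (length(d) - 1L)
      gaps <- if (length(d) > 1L) {
        g <- stats::runif(length(d) - 1L); 1L + floor(g / sum(g) * max(0, slack) * 0.5)
      } else integer(0)
      off0 <- if (slack > 0) sample.int(max(1L, slack), 1L) - 1L else 0L
      starts <- off0 + cumsum(c(0L, d[-length(d)] + gaps)) + (w - 1L) * WINDOW_S
      keep <- starts + d <= w * WINDOW_S
      if (!any(keep)) next
      maxd <- ifelse(stats::runif(sum(keep)) < params$deep_dive_prob,
                     1 + stats::rexp(sum(keep), 1 / params$dive_depth_scale),
                     stats::runif(sum(keep), 0.1, 0.9))
      bouts_all[[length(bouts_all) + 1L]] <- tibble::tibble(
        start_s = starts[keep], duration_s = d[keep], max_depth_m = maxd)
      wet_win[w] <- TRUE
    }
    bouts <- if (length(bouts_all)) dplyr::bind_rows(bouts_all) else {
      tibble::tibble(start_s = integer(0), duration_s = integer(0),
                     max_depth_m = numeric(0))
    }

    n_sec <- n_win * WINDOW_S
    wet <- logical(n_sec)
    depth <- numeric(n_sec)
    if (nrow(bouts)) {
      for (k in seq_len(nrow(bouts))) {
        s <- bouts$start_s[k] + 1L
        e <- bouts$start_s[k] + bouts$duration_s[k]
        wet[s:e] <- TRUE
        dur <- bouts$duration_s[k]
        prof <- rep(0.3, dur)
        if (bouts$max_depth_m[k] > 0.3 && dur >= 3L) {
          dl <- min(dur, max(3L, round(stats::runif(1, 20, 90))))
          d0 <- sample.int(dur - dl + 1L, 1L)
          tri <- 1 - abs(seq(-1, 1, length.out = dl))
          prof[d0:(d0 + dl - 1L)] <-
            pmax(0.3, bouts$max_depth_m[k] * tri)
        }
        depth[s:e] <- prof
      }
    }

    # encode the stream per dialect
    if (tag_type == "TDR") {
      samp <- seq(1L, n_sec, by = 10L)
      cond <- ifelse(wet[samp], stats::runif(length(samp), 20, 80),
                     stats::runif(length(samp), 150, 250))
      stream <- tibble::tibble(time = start + samp - 1L,
                               conductivity = cond, depth_m = depth[samp])
    } else {
      stream <- tibble::tibble(time = start + seq_len(n_sec) - 1L,
                               conductivity = as.numeric(wet),
                               depth_m = if (tag_type == "SMRU") depth else NA_real_)
    }

    # GPS fixes every 2 h at window starts, suppressed while wet (the first
    # fix, at capture, is always present)
    fix_sec <- (seq_len(n_win) - 1L) * WINDOW_S + 1L
    fix_ok <- !wet[fix_sec]
    fix_ok[1] <- TRUE
    track <- tibble::tibble(time = times[fix_ok], lat = lat_t[fix_ok],
                            lon = lon_t[fix_ok], quality = "G")

    windows <- tibble::tibble(
      bear_id = bear_id, status = reproductive_status, time = times,
      date = dates, julian_day = doy, step = seq_len(n_win),
      ice_pct = ice_pct, p_true = dw$p, any_swim = wet_win)

    structure(
      list(bear_id = bear_id, tag_type = tag_type, start = start,
           end = start + n_sec, reproductive_status = reproductive_status,
           stream = stream, track = track, bouts = bouts, windows = windows),
      class = "deployment")
  })
}

#' @export
print.deployment <- function(x, ...) {
  cat(sprintf("<deployment> %s [%s] %s to %s (%s)\n", x$bear_id, x$tag_type,
              format(x$start, "%Y-%m-%d"), format(x$end, "%Y-%m-%d"),
              x$reproductive_status))
  cat(sprintf("  %d stream samples, %d GPS fixes, %d swim bouts\n",
              nrow(x$stream), nrow(x$track), nrow(x$bouts)))
  invisible(x)
}

#' Generate a self-contained fixture cohort
#'
#' Builds a seeded bundle emulating the structure of a multi-year polar bear
#' biologging study: one deployment per bear with tag types cycling through
#' the three dialects, a configurable fraction of females with
#' cubs-of-the-year and of offshore-ranging bears, a shared sea-ice field
#' and coastline, and a metadata table. Optionally writes every piece in the
#' package's standard on-disk formats (stream/track/metadata CSV, ice
#' CSV+JSON, coastline GeoJSON).
#'
#' @param n_bears number of bears (one deployment each).
#' @param seed integer master seed; identical seeds give identical bundles.
#' @param dir optional directory; when non-`NULL` all files are written
#'   there.
#' @param duration_days deployment length per bear.
#' @param start_date first deployment day.
#' @param frac_coy fraction of bears with cubs-of-the-year.
#' @param frac_offshore fraction of bears making an offshore excursion.
#' @param params a [behaviour_params]; its `seed` is overridden by `seed`.
#'
#' @return A list with `deployments` (list of [simulate_deployment()]
#'   results), `ice`, `coast`, `metadata` (tibble), and `dir`.
#' @export
make_fixture_cohort <- function(n_bears, seed, dir = NULL,
                                duration_days = 30,
                                start_date = "2015-04-01",
                                frac_coy = 0.3, frac_offshore = 0.3,
                                params = behaviour_params()) {
  stopifnot_scalar_number(n_bears, "n_bears", positive = TRUE)
  n_bears <- as.integer(n_bears)
  start_date <- as.Date(start_date)
  ice <- simulate_ice_field(seed, n_days = duration_days + 2L,
                            start_date = start_date - 1L)
  coast <- simulate_coastline(seed)
  n_coy <- round(frac_coy * n_bears)
  n_off <- round(frac_offshore * n_bears)
  statuses <- rep("NO_CUBS", n_bears)
  if (n_coy > 0) statuses[seq_len(n_coy)] <- "COY"
  # remaining non-COY bears alternate NO_CUBS / YEARLING
  rest <- which(statuses == "NO_CUBS")
  statuses[rest[seq_along(rest) %% 2L == 0L]] <- "YEARLING"
  offshore <- rep(FALSE, n_bears)
  if (n_off > 0) offshore[n_bears - seq_len(n_off) + 1L] <- TRUE
  tags <- rep(c("TDR", "TELONICS", "SMRU"), length.out = n_bears)

  deployments <- lapply(seq_len(n_bears), function(i) {
    simulate_deployment(params, tags[i], duration_days, ice = ice,
                        coast = coast, bear_id = sprintf("B%03d", i),
                        start = paste(start_date, "00:00:00"),
                        reproductive_status = statuses[i],
                        offshore = offshore[i],
                        seed = child_seed(seed, sprintf("bear%03d", i)))
  })
  metadata <- tibble::tibble(
    bear_id = vapply(deployments, `[[`, "", "bear_id"),
    tag_type = tags,
    start = format(start_date),
    end = format(start_date + duration_days),
    reproductive_status = statuses)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "streams"), showWarnings = FALSE)
    dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
    for (d in deployments) {
      write_stream_csv(d$stream, file.path(dir, "streams",
                                           paste0(d$bear_id, "_stream.csv")))
      write_track_csv(d$track, file.path(dir, "tracks",
                                         paste0(d$bear_id, "_track.csv")))
    }
    utils::write.csv(metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE, quote = FALSE)
    write_ice(ice, file.path(dir, "ice"))
    write_coastline(coast, file.path(dir, "coast.geojson"))
  }
  list(deployments = deployments, ice = ice, coast = coast,
       metadata = metadata, dir = dir)
}

# ---- stream / track CSV i/o -------------------------------------------------

TS_FMT <- "%Y-%m-%d %H:%M:%S"

#' Sensor-stream and track CSV files
#'
#' Streams are stored as `timestamp_utc, conductivity, depth_m` (conductivity
#' is sensor counts for archival tags and a 0/1 wet flag for collars); tracks
#' as `timestamp_utc, lat, lon, quality`. Output is deterministic: fixed
#' timestamp format and fixed numeric formatting.
#'
#' @param stream,track tibbles as produced by [simulate_deployment()].
#' @param path file path.
#' @return The writers return `path` invisibly; readers return tibbles with
#'   POSIXct `time` (UTC).
#' @export
write_stream_csv <- function(stream, path) {
  df <- data.frame(
    timestamp_utc = format(stream$time, TS_FMT, tz = "UTC"),
    conductivity = sprintf("%.3f", stream$conductivity),
    depth_m = ifelse(is.na(stream$depth_m), "",
                     sprintf("%.2f", stream$depth_m)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"))
  tibble::tibble(time = as_utc(df$timestamp_utc),
                 conductivity = df$conductivity, depth_m = df$depth_m)
}

#' @rdname write_stream_csv
#' @export
write_track_csv <- function(track, path) {
  df <- data.frame(
    timestamp_utc = format(track$time, TS_FMT, tz = "UTC"),
    lat = sprintf("%.6f", track$lat), lon = sprintf("%.6f", track$lon),
    quality = track$quality)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path,
                        colClasses = c("character", "numeric", "numeric",
                                       "character"))
  tibble::tibble(time = as_utc(df$timestamp_utc), lat = df$lat,
                 lon = df$lon, quality = df$quality)
}
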
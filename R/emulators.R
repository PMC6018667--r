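#' Classify wet/dry from TDR conductivity counts
#'
#' Archival time-depth recorders log a raw conductivity count every 10 s;
#' sea water reads far below 100 counts, air far above. A sample is wet if
#' and only if its reading is strictly below 100 (a reading of exactly 100
#' is dry). Missing readings propagate as missing flags — they are never
#' imputed as dry.
#'
#' @param reading numeric vector of conductivity counts.
#' @return Logical vector: `TRUE` = wet, `NA` where the reading is missing.
#' @export
classify_wet_tdr <- function(reading) {
  if (!is.numeric(reading)) stop("`reading` must be numeric")
  reading < 100
}

#' Hourly percent time in water from a TDR stream
#'
#' Sums 10-s wet/dry classifications into clock-hour summaries:
#' `pct_wet = 100 * wet samples / samples present in the hour`. Hours with
#' no samples are omitted. The stream must be sampled on a regular 10-s
#' grid; an irregular interval is an error naming the first offending gap.
#'
#' @param stream tibble with `time` (POSIXct UTC) and `conductivity`
#'   (counts), as read by [read_stream_csv()].
#' @return Tibble of hourly summary windows: `window_start`, `window_h`
#'   (= 1), `pct_wet`, `n_samples`. Hours whose samples are all missing get
#'   `pct_wet = NA`.
#' @export
hourly_pct_wet_tdr <- function(stream) {
  stopifnot(all(c("time", "conductivity") %in% names(stream)))
  if (nrow(stream) > 1L) {
    dt <- as.numeric(diff(stream$time), units = "secs")
    bad <- which(dt != 10)
    if (length(bad)) {
      stop(sprintf(
        "irregular TDR sampling: %.0f s gap after %s (expected 10 s)",
        dt[bad[1]], format(stream$time[bad[1]], TS_FMT, tz = "UTC")),
        call. = FALSE)
    }
  }
  wet <- classify_wet_tdr(stream$conductivity)
  hour <- as.POSIXct(floor(as.numeric(stream$time) / 3600) * 3600,
                     origin = "1970-01-01", tz = "UTC")
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(hour = hour, wet = wet), hour),
    pct_wet = 100 * mean(wet, na.rm = TRUE),
    n_samples = sum(!is.na(wet)), .groups = "drop")
  agg$pct_wet[agg$n_samples == 0L] <- NA_real_
  tibble::tibble(window_start = agg$hour, window_h = 1,
                 pct_wet = agg$pct_wet, n_samples = agg$n_samples)
}

#' Detect swim events from a 1-s wet/dry sequence
#'
#' Applies the collar firmware rule: a swim starts once `start_run`
#' consecutive wet seconds are seen (5 s for Telonics, 12 s for SMRU) and
#' ends at the last wet second before the next dry second. The whole
#' qualifying wet run counts as the swim — the start-run requirement is a
#' detection criterion, not a trim — so the sum of event durations equals
#' the wet time of qualifying runs. Wet runs shorter than `start_run`
#' produce no event and contribute no time in water. A single dry second
#' terminates an event; a later qualifying run starts a new one. Missing
#' flags break runs without counting as wet.
#'
#' @param wet logical vector at 1-s resolution (`TRUE` = wet).
#' @param start_run minimum run of wet seconds that triggers detection.
#' @param end_run dry seconds ending a swim (the firmware uses 1; other
#'   values are not supported).
#' @param t0 POSIXct time of the first sample (defaults to an arbitrary
#'   epoch-aligned origin).
#' @param depth optional numeric vector of depths (m) aligned with `wet`,
#'   used to attach each event's maximum depth.
#' @return Tibble of disjoint, ordered events: `start` (POSIXct),
#'   `duration_s`, `max_depth_m` (`NA` when no depth channel).
#' @export
detect_swims <- function(wet, start_run, end_run = 1L,
                         t0 = as_utc("2000-01-01 00:00:00"), depth = NULL) {
  stopifnot_scalar_number(start_run, "start_run", positive = TRUE)
  if (end_run != 1L) stop("only end_run = 1 (the firmware rule) is supported")
  empty <- tibble::tibble(start = as_utc(character(0)),
                          duration_s = integer(0), max_depth_m = numeric(0))
  if (length(wet) == 0L) return(empty)
  flag <- !is.na(wet) & wet
  r <- rle(flag)
  len <- r$lengths
  ends <- cumsum(len)
  starts <- ends - len + 1L
  keep <- r$values & len >= start_run
  if (!any(keep)) return(empty)
  s <- starts[keep]; d <- len[keep]
  maxd <- if (is.null(depth)) rep(NA_real_, length(s)) else {
    if (any(depth < 0, na.rm = TRUE)) stop("negative depth in stream")
    vapply(seq_along(s), function(i) {
      suppressWarnings(max(depth[s[i]:(s[i] + d[i] - 1L)], na.rm = TRUE))
    }, numeric(1))
  }
  maxd[is.infinite(maxd)] <- NA_real_
  tibble::tibble(start = t0 + (s - 1L), duration_s = as.integer(d),
                 max_depth_m = maxd)
}

# Clip swim events to an aligned window grid. Returns one row per
# (event, window) intersection with the clipped duration and, when a 1-s
# depth series is supplied, the max depth over the clipped seconds.
clip_swims_to_windows <- function(swims, window_s, depth = NULL, t0 = NULL) {
  if (nrow(swims) == 0L) {
    return(tibble::tibble(window_start = as_utc(character(0)),
                          dur_s = numeric(0), max_depth_m = numeric(0)))
  }
  s0 <- as.numeric(swims$start)
  out <- vector("list", nrow(swims))
  for (i in seq_len(nrow(swims))) {
    a <- s0[i]; bnd <- a + swims$duration_s[i]  # [a, bnd)
    w <- seq(floor(a / window_s), floor((bnd - 1) / window_s))
    ws <- w * window_s
    lo <- pmax(a, ws); hi <- pmin(bnd, ws + window_s)
    md <- rep(swims$max_depth_m[i], length(w))
    if (!is.null(depth) && !is.null(t0)) {
      o0 <- as.numeric(t0)
      md <- vapply(seq_along(w), function(j) {
        ix <- (lo[j] - o0 + 1):(hi[j] - o0)
        ix <- ix[ix >= 1 & ix <= length(depth)]
        if (!length(ix)) return(NA_real_)
        suppressWarnings(max(depth[ix], na.rm = TRUE))
      }, numeric(1))
      md[is.infinite(md)] <- NA_real_
    }
    out[[i]] <- tibble::tibble(window_start = ws, dur_s = hi - lo,
                               max_depth_m = md)
  }
  res <- dplyr::bind_rows(out)
  res$window_start <- as.POSIXct(res$window_start, origin = "1970-01-01",
                                 tz = "UTC")
  res
}

#' SMRU-style 4-hour summary windows
#'
#' Aggregates detected swims (12-s start rule) into the summaries an SMRU
#' collar stores per 4-h window: percent time in water, maximum depth, and
#' average and maximum swim duration. Swims spanning a window boundary are
#' clipped: each window is credited with its own seconds (keeping
#' percentages provably <= 100), and the clipped parts enter both windows'
#' duration statistics. Only detected swims count toward time in water —
#' sub-threshold wet runs contribute nothing. Windows without swims report
#' 0% and empty depth/duration fields.
#'
#' @param swims tibble from [detect_swims()] (use `start_run = 12`).
#' @param window_h window length in hours (firmware uses 4).
#' @param depth optional 1-s depth vector with its origin `t0`, used for
#'   exact in-window maximum depths; otherwise each event's own max depth
#'   is used for every window it touches.
#' @param t0 POSIXct origin of `depth`.
#' @param span optional POSIXct length-2 vector; windows covering this span
#'   are reported even if swim-free. Default: from first to last swim.
#' @return Tibble: `window_start`, `window_h`, `pct_wet`, `max_depth_m`,
#'   `mean_dur_s`, `max_dur_s`.
#' @export
summarize_windows_smru <- function(swims, window_h = 4, depth = NULL,
                                   t0 = NULL, span = NULL) {
  window_s <- round(window_h * 3600)
  clipped <- clip_swims_to_windows(swims, window_s, depth = depth, t0 = t0)
  agg <- dplyr::summarise(
    dplyr::group_by(clipped, window_start),
    pct_wet = 100 * sum(dur_s) / window_s,
    max_depth_m = if (all(is.na(max_depth_m))) NA_real_ else
      max(max_depth_m, na.rm = TRUE),
    mean_dur_s = mean(dur_s), max_dur_s = max(dur_s), .groups = "drop")
  if (!is.null(span)) {
    grid <- seq(floor(as.numeric(span[1]) / window_s) * window_s,
                floor((as.numeric(span[2]) - 1) / window_s) * window_s,
                by = window_s)
    grid <- as.POSIXct(grid, origin = "1970-01-01", tz = "UTC")
    miss <- setdiff(as.numeric(grid), as.numeric(agg$window_start))
    if (length(miss)) {
      agg <- dplyr::bind_rows(agg, tibble::tibble(
        window_start = as.POSIXct(miss, origin = "1970-01-01", tz = "UTC"),
        pct_wet = 0, max_depth_m = NA_real_, mean_dur_s = NA_real_,
        max_dur_s = NA_real_))
    }
  }
  agg <- dplyr::arrange(agg, window_start)
  tibble::tibble(window_start = agg$window_start, window_h = window_h,
                 pct_wet = agg$pct_wet, max_depth_m = agg$max_depth_m,
                 mean_dur_s = agg$mean_dur_s, max_dur_s = agg$max_dur_s)
}

#' Telonics-style hourly percent time in water
#'
#' Aggregates detected swims (5-s start rule) into the hourly percent time
#' in water a Telonics collar transmits:
#' `pct_wet = 100 * clipped swim seconds / 3600`.
#'
#' @inheritParams summarize_windows_smru
#' @param swims tibble from [detect_swims()] (use `start_run = 5`).
#' @return Tibble: `window_start`, `window_h` (= 1), `pct_wet`.
#' @export
hourly_pct_wet_telonics <- function(swims, span = NULL) {
  w <- summarize_windows_smru(swims, window_h = 1, span = span)
  tibble::tibble(window_start = w$window_start, window_h = 1,
                 pct_wet = w$pct_wet)
}

#' Argos-style random subsampling of summary windows
#'
#' SMRU collars transmit only a random subset of their stored summaries via
#' Argos; the full record is recovered only if the instrument is retrieved.
#' Each window is retained independently with probability `fraction`, under
#' a fixed seed (same seed, same subset). The caller keeps the full input
#' as the "recovered" record.
#'
#' @param windows tibble of summary windows.
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed.
#' @return The retained subset, in original order.
#' @export
argos_subsample <- function(windows, fraction, seed) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]")
  }
  if (fraction == 1) return(windows)
  with_seed(child_seed(seed, "argos"), {
    windows[stats::runif(nrow(windows)) < fraction, , drop = FALSE]
  })
}

#' Daily maximum dive depth over days with registered swims
#'
#' One value per UTC day holding the maximum depth over that day's swims
#' (each swim assigned to the day it starts). Days without swims are
#' excluded — depth histograms are defined over days with registered
#' swimming only. Swims without a depth channel are ignored.
#'
#' @param swims tibble from [detect_swims()] with `max_depth_m`.
#' @return Tibble: `date`, `max_depth_m`, `n_swims`.
#' @export
daily_max_depth <- function(swims) {
  if (any(swims$max_depth_m < 0, na.rm = TRUE)) stop("negative depth")
  sw <- swims[!is.na(swims$max_depth_m), , drop = FALSE]
  if (nrow(sw) == 0L) {
    return(tibble::tibble(date = as.Date(character(0)),
                          max_depth_m = numeric(0), n_swims = integer(0)))
  }
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(date = utc_day(sw$start),
                                   d = sw$max_depth_m), date),
    max_depth_m = max(d), n_swims = dplyr::n(), .groups = "drop")
}
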
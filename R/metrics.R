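#' Daily time-in-water series
#'
#' Helpers reducing tag outputs to one row per bear-day: percent time in
#' water (wet time over recorded time) and an any-swim flag. For archival
#' TDRs a bear counts as having swum on a day if any 10-s sample is wet;
#' for collars, if any detected swim starts or continues that day — each
#' tag's own detection dialect, since cohort summaries pool all sensor
#' types.
#'
#' @param stream TDR tibble (`time`, `conductivity`).
#' @return Tibble: `date`, `pct_tiw` (0--100), `any_swim`, `n_samples`.
#' @export
daily_tiw_tdr <- function(stream) {
  wet <- classify_wet_tdr(stream$conductivity)
  d <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(date = utc_day(stream$time), wet = wet),
                    date),
    pct_tiw = 100 * mean(wet, na.rm = TRUE),
    any_swim = any(wet, na.rm = TRUE),
    n_samples = sum(!is.na(wet)), .groups = "drop")
  d$pct_tiw[d$n_samples == 0L] <- NA_real_
  d
}

#' @rdname daily_tiw_tdr
#' @param swims tibble from [detect_swims()].
#' @param span POSIXct length-2: period the tag recorded over; days inside
#'   the span with no swims get `pct_tiw = 0`.
#' @export
daily_tiw_swims <- function(swims, span) {
  days <- seq(utc_day(span[1]), utc_day(span[2] - 1), by = "day")
  clipped <- clip_swims_to_windows(swims, 86400)
  agg <- dplyr::summarise(
    dplyr::group_by(clipped, date = utc_day(window_start)),
    wet_s = sum(dur_s), .groups = "drop")
  out <- tibble::tibble(date = days)
  out$wet_s <- agg$wet_s[match(out$date, agg$date)]
  out$wet_s[is.na(out$wet_s)] <- 0
  tibble::tibble(date = out$date, pct_tiw = 100 * out$wet_s / 86400,
                 any_swim = out$wet_s > 0,
                 n_samples = rep(86400L, length(days)))
}

#' Monthly mean time in water per bear
#'
#' Arithmetic mean of the daily percent-time-in-water values within each
#' bear-month, reported only for months with at least `min_days` days of
#' data (months with fewer are omitted entirely).
#'
#' @param daily tibble with `bear_id`, `date`, `pct_tiw` and optionally
#'   `reproductive_status` / `strategy` (carried through).
#' @param min_days minimum days of data per bear-month (default 5).
#' @return Tibble: `bear_id`, `year_month` (`"YYYY-MM"`), `month`
#'   (integer), `mean_pct_tiw`, `n_days`, plus any carried columns.
#' @export
monthly_means <- function(daily, min_days = 5) {
  stopifnot(all(c("bear_id", "date", "pct_tiw") %in% names(daily)))
  if (any(daily$pct_tiw < 0 | daily$pct_tiw > 100, na.rm = TRUE)) {
    stop("daily pct_tiw must lie in [0, 100]")
  }
  d <- daily[!is.na(daily$pct_tiw), , drop = FALSE]
  d$year_month <- format(d$date, "%Y-%m")
  carry <- intersect(c("reproductive_status", "strategy"), names(d))
  g <- dplyr::group_by(d, bear_id, year_month)
  out <- dplyr::summarise(
    g, month = as.integer(format(date[1], "%m")),
    mean_pct_tiw = mean(pct_tiw), n_days = dplyr::n(),
    dplyr::across(dplyr::all_of(carry), ~ .x[1]), .groups = "drop")
  out[out$n_days >= min_days, , drop = FALSE]
}

#' Proportion of instrumented bears that swam, by period
#'
#' For each calendar month of the year, the fraction of observation units
#' with at least one swim, where a unit is a bear-day (`"day"`), a
#' bear-ISO-week (`"week"`, assigned to the month of its first observed
#' day) or a bear-month (`"month"`). Only bears with data in a unit count
#' toward its denominator.
#'
#' @param daily tibble with `bear_id`, `date`, `any_swim`.
#' @param period `"day"`, `"week"` or `"month"`.
#' @return Tibble: `period`, `month`, `prevalence` (0--1), `n_units`.
#' @export
swim_prevalence <- function(daily, period = c("day", "week", "month")) {
  period <- match.arg(period)
  d <- daily[!is.na(daily$any_swim), , drop = FALSE]
  unit <- switch(period,
    day = format(d$date, "%Y-%m-%d"),
    week = format(d$date, "%G-W%V"),
    month = format(d$date, "%Y-%m"))
  u <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bear_id = d$bear_id, unit = unit,
                                   date = d$date, any = d$any_swim),
                    bear_id, unit),
    month = as.integer(format(min(date), "%m")),
    swam = any(any), .groups = "drop")
  dplyr::summarise(dplyr::group_by(u, month),
                   prevalence = mean(swam), n_units = dplyr::n(),
                   .groups = "drop") |>
    dplyr::mutate(period = period, .before = 1)
}

#' Reproductive-status contrast in monthly time in water
#'
#' Compares females with cubs-of-the-year against the pooled other classes
#' (no cubs and yearlings, which show no overall difference) for one
#' calendar month, via an ordinary least-squares regression of the monthly
#' mean percent time in water on the group indicator.
#'
#' @param bear_months tibble from [monthly_means()] with
#'   `reproductive_status`.
#' @param month calendar month of year (1--12).
#' @return One-row tibble: `month`, `estimate` (COY minus others, in
#'   percentage points), `se`, `p_value`, `n_coy`, `n_other`.
#' @export
reproductive_contrast <- function(bear_months, month) {
  bm <- bear_months[bear_months$month == month, , drop = FALSE]
  coy <- bm$reproductive_status == "COY"
  if (sum(coy) < 2 || sum(!coy) < 2) {
    stop(sprintf("month %d: need >= 2 bear-months in each group (COY %d, other %d)",
                 month, sum(coy), sum(!coy)), call. = FALSE)
  }
  fit <- stats::lm(mean_pct_tiw ~ coy, data = data.frame(
    mean_pct_tiw = bm$mean_pct_tiw, coy = coy))
  sm <- summary(fit)$coefficients
  tibble::tibble(month = month, estimate = sm["coyTRUE", "Estimate"],
                 se = sm["coyTRUE", "Std. Error"],
                 p_value = sm["coyTRUE", "Pr(>|t|)"],
                 n_coy = sum(coy), n_other = sum(!coy))
}

#' Classify space-use strategy from a track
#'
#' A bear is `"OFFSHORE"` if any location lies farther than
#' `offshore_dist_km` from every island polygon (it made at least one
#' offshore excursion); otherwise `"UNCLASSIFIED"` if the track does not
#' span an entire summer (no year in which every month of `summer_months`
#' has at least one fix); otherwise `"LOCAL"`. The distance threshold
#' replaces visual inspection of tracks with a reproducible rule.
#'
#' @param track tibble with `time`, `lat`, `lon`.
#' @param coast a [coastline].
#' @param offshore_dist_km excursion threshold in km (default 50).
#' @param summer_months months that must all be covered to call a track
#'   full-summer (default June--September).
#' @return One of `"OFFSHORE"`, `"LOCAL"`, `"UNCLASSIFIED"`.
#' @export
classify_strategy <- function(track, coast, offshore_dist_km = 50,
                              summer_months = 6:9) {
  if (nrow(track) == 0L) stop("empty track")
  dist <- distance_to_land(track$lat, track$lon, coast)
  if (any(dist > offshore_dist_km)) return("OFFSHORE")
  ym <- data.frame(year = format(as_utc(track$time), "%Y"),
                   month = as.integer(format(as_utc(track$time), "%m")))
  covered <- vapply(split(ym$month, ym$year),
                    function(m) all(summer_months %in% m), logical(1))
  if (!any(covered)) return("UNCLASSIFIED")
  "LOCAL"
}

#' Summarize a long-distance swim
#'
#' Characterizes a gap-bounded trip: straight-line (great-circle) distance
#' between the bounding fixes, trip duration, total hours swimming within
#' the trip (swim time clipped to the trip), and the longest single
#' continuous swim.
#'
#' @param trip one-row tibble (or list) with `start`, `end`, `start_lat`,
#'   `start_lon`, `end_lat`, `end_lon` — the last fix before and first fix
#'   after the gap.
#' @param swims tibble from [detect_swims()] for the same bear.
#' @return One-row tibble: `start`, `end`, `distance_km`, `trip_hours`,
#'   `swim_hours`, `max_continuous_hours`.
#' @export
summarize_long_swim <- function(trip, swims) {
  t0 <- as_utc(trip$start); t1 <- as_utc(trip$end)
  if (t1 <= t0) stop("trip end must be after trip start")
  lo <- as.numeric(t0); hi <- as.numeric(t1)
  s <- pmax(as.numeric(swims$start), lo)
  e <- pmin(as.numeric(swims$start) + swims$duration_s, hi)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  # total wet time is the measure of the interval union (detector events
  # are disjoint, but guard against overlapping inputs)
  if (length(s)) {
    o <- order(s)
    s <- s[o]; e <- e[o]
    merged_s <- s[1]; merged_e <- e[1]; total <- 0
    for (i in seq_along(s)[-1]) {
      if (s[i] <= merged_e) {
        merged_e <- max(merged_e, e[i])
      } else {
        total <- total + (merged_e - merged_s)
        merged_s <- s[i]; merged_e <- e[i]
      }
    }
    total <- total + (merged_e - merged_s)
  } else total <- 0
  tibble::tibble(
    start = t0, end = t1,
    distance_km = great_circle_km(trip$start_lat, trip$start_lon,
                                  trip$end_lat, trip$end_lon),
    trip_hours = (hi - lo) / 3600,
    swim_hours = total / 3600,
    max_continuous_hours = if (length(s)) max(e - s) / 3600 else 0)
}

#' Histogram of daily maximum dive depths
#'
#' Bins daily maximum depths (days with registered swims only) into 1-m
#' bins `[k, k + 1)` and reports the share of days confined to the top
#' metre, per bear and averaged across bears.
#'
#' @param daily_depths tibble with `max_depth_m` and optionally `bear_id`.
#' @return List: `histogram` (`bin_lo`, `bin_hi`, `n`), `pct_surface_by_bear`
#'   (`bear_id`, `pct_surface`, `n_days`), `pct_surface_mean`,
#'   `pct_surface_sd`.
#' @export
depth_histogram <- function(daily_depths) {
  d <- daily_depths$max_depth_m
  if (any(d < 0, na.rm = TRUE)) stop("negative depth")
  d <- d[!is.na(d)]
  if (length(d) == 0L) {
    return(list(histogram = tibble::tibble(bin_lo = integer(0),
                                           bin_hi = integer(0),
                                           n = integer(0)),
                pct_surface_by_bear = tibble::tibble(
                  bear_id = character(0), pct_surface = numeric(0),
                  n_days = integer(0)),
                pct_surface_mean = NA_real_, pct_surface_sd = NA_real_))
  }
  bin <- floor(d)
  tab <- table(bin)
  hist <- tibble::tibble(bin_lo = as.integer(names(tab)),
                         bin_hi = as.integer(names(tab)) + 1L,
                         n = as.integer(tab))
  by_bear <- if ("bear_id" %in% names(daily_depths)) {
    dd <- daily_depths[!is.na(daily_depths$max_depth_m), , drop = FALSE]
    dplyr::summarise(dplyr::group_by(dd, bear_id),
                     pct_surface = 100 * mean(max_depth_m < 1),
                     n_days = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(bear_id = "all", pct_surface = 100 * mean(d < 1),
                   n_days = length(d))
  }
  list(histogram = hist, pct_surface_by_bear = by_bear,
       pct_surface_mean = mean(by_bear$pct_surface),
       pct_surface_sd = if (nrow(by_bear) > 1) stats::sd(by_bear$pct_surface)
         else NA_real_)
}
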
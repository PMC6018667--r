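#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over
#' coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (WGS84).
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Interpolate gaps in a GPS track
#'
#' Collar fixes are lost while a bear swims (submerged antenna), leaving
#' gaps. Gaps strictly shorter than `max_gap_h` are filled with points
#' placed on the regular `step_h`-hour UTC clock grid strictly inside the
#' gap, linear in time in latitude and longitude between the bounding
#' fixes; gaps of `max_gap_h` or longer are left empty. Interpolation is in
#' geographic degrees, adequate at high-latitude regional scales and gap
#' lengths of a day or two.
#'
#' @param track tibble with `time` (POSIXct, strictly increasing), `lat`,
#'   `lon`.
#' @param max_gap_h gaps at or above this length (hours) are not filled
#'   (default 48, the cap chosen so long-swim gaps are still bridged).
#' @param step_h spacing of the interpolation grid in hours (default 2,
#'   the nominal fix schedule).
#' @return Tibble `time, lat, lon, interpolated` (logical), ordered in
#'   time; original rows keep any extra columns' values dropped.
#' @export
interpolate_track <- function(track, max_gap_h = 48, step_h = 2) {
  stopifnot(all(c("time", "lat", "lon") %in% names(track)))
  if (nrow(track) < 2L) {
    return(tibble::tibble(time = as_utc(track$time), lat = track$lat,
                          lon = track$lon,
                          interpolated = rep(FALSE, nrow(track))))
  }
  tt <- as.numeric(as_utc(track$time))
  if (any(diff(tt) <= 0)) stop("track times must be strictly increasing")
  step_s <- round(step_h * 3600)
  max_gap_s <- max_gap_h * 3600
  pieces <- list(tibble::tibble(time = tt, lat = track$lat, lon = track$lon,
                                interpolated = FALSE))
  for (i in seq_len(nrow(track) - 1L)) {
    gap <- tt[i + 1L] - tt[i]
    if (gap >= max_gap_s) next                       # "shorter than" is strict
    grid <- seq(ceiling(tt[i] / step_s) * step_s,
                floor(tt[i + 1L] / step_s) * step_s, by = step_s)
    grid <- grid[grid > tt[i] & grid < tt[i + 1L]]
    if (!length(grid)) next
    f <- (grid - tt[i]) / gap
    pieces[[length(pieces) + 1L]] <- tibble::tibble(
      time = grid,
      lat = track$lat[i] + f * (track$lat[i + 1L] - track$lat[i]),
      lon = track$lon[i] + f * (track$lon[i + 1L] - track$lon[i]),
      interpolated = TRUE)
  }
  out <- dplyr::arrange(dplyr::bind_rows(pieces), time)
  out$time <- as.POSIXct(out$time, origin = "1970-01-01", tz = "UTC")
  out
}

#' Time in water for the 2-hour window centred on a location
#'
#' For each location time, computes the proportion of the half-open 2-h
#' window `[t - 1 h, t + 1 h)` spent in water, using the study's source
#' precedence: if Telonics hourly summaries cover the window, the mean of
#' the overlapped hourly percentages (divided by 100) is used; otherwise,
#' if a TDR stream covers it, the proportion of 10-s samples in the window
#' that are wet; otherwise missing. When both sources exist for a window,
#' Telonics wins.
#'
#' @param times POSIXct vector of location times.
#' @param telonics_hours optional tibble of hourly summaries
#'   (`window_start`, `pct_wet`) from [hourly_pct_wet_telonics()].
#' @param tdr_stream optional TDR tibble (`time`, `conductivity`).
#' @return Numeric vector of proportions in \[0, 1\], `NA` where neither
#'   source covers the window.
#' @export
window_time_in_water <- function(times, telonics_hours = NULL,
                                 tdr_stream = NULL) {
  times <- as_utc(times)
  n <- length(times)
  out <- rep(NA_real_, n)
  tel_t <- if (!is.null(telonics_hours)) as.numeric(telonics_hours$window_start)
  tdr_t <- NULL; tdr_wet <- NULL
  if (!is.null(tdr_stream)) {
    tdr_t <- as.numeric(tdr_stream$time)
    tdr_wet <- classify_wet_tdr(tdr_stream$conductivity)
  }
  for (i in seq_len(n)) {
    lo <- as.numeric(times[i]) - 3600
    hi <- lo + 7200
    if (!is.null(tel_t)) {
      # hours overlapping [lo, hi)
      h0 <- floor(lo / 3600) * 3600
      hours <- seq(h0, hi - 1, by = 3600)
      hours <- hours[hours + 3600 > lo]
      j <- match(hours, tel_t)
      if (!anyNA(j) && !anyNA(telonics_hours$pct_wet[j])) {
        w <- pmin(hours + 3600, hi) - pmax(hours, lo)   # overlap weights
        out[i] <- sum(w * telonics_hours$pct_wet[j]) / sum(w) / 100
        next
      }
    }
    if (!is.null(tdr_t)) {
      k <- tdr_t >= lo & tdr_t < hi & !is.na(tdr_wet)
      if (any(k)) out[i] <- mean(tdr_wet[k])
    }
  }
  out
}

#' Attach 2-hour time in water to a track
#'
#' Convenience wrapper adding a `tiw_2h` column to an (interpolated) track
#' via [window_time_in_water()].
#'
#' @param track tibble with a `time` column.
#' @inheritParams window_time_in_water
#' @return `track` with `tiw_2h` added.
#' @export
attach_time_in_water <- function(track, telonics_hours = NULL,
                                 tdr_stream = NULL) {
  track$tiw_2h <- window_time_in_water(track$time, telonics_hours,
                                       tdr_stream)
  track
}

#' Gap-bounded trips in a raw track
#'
#' Identifies candidate swimming trips as gaps in the raw (uninterpolated)
#' fix record of at least `min_gap_h` hours; the last fix before and the
#' first fix after a gap are taken as the start and end of the trip.
#'
#' @param track tibble with `time`, `lat`, `lon` (raw fixes only).
#' @param min_gap_h minimum gap length (hours) to call a trip.
#' @return Tibble: `start`, `end`, `start_lat`, `start_lon`, `end_lat`,
#'   `end_lon`, `gap_h`.
#' @export
find_gap_trips <- function(track, min_gap_h = 4) {
  if (nrow(track) < 2L) {
    return(tibble::tibble(start = as_utc(character(0)),
                          end = as_utc(character(0)),
                          start_lat = numeric(0), start_lon = numeric(0),
                          end_lat = numeric(0), end_lon = numeric(0),
                          gap_h = numeric(0)))
  }
  dt <- as.numeric(diff(track$time), units = "hours")
  i <- which(dt >= min_gap_h)
  tibble::tibble(start = track$time[i], end = track$time[i + 1L],
                 start_lat = track$lat[i], start_lon = track$lon[i],
                 end_lat = track$lat[i + 1L], end_lon = track$lon[i + 1L],
                 gap_h = dt[i])
}
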
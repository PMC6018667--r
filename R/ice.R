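#' Sea-ice concentration fields
#'
#' An `ice_field` holds a daily sequence of gridded sea-ice concentrations
#' (percent cover, 0--100) on a regular local grid of square cells, emulating
#' the structure of the 12.5-km, 5-day-median passive-microwave products used
#' to attach ice covariates to polar bear locations. The grid is anchored at
#' the centre of cell `[1, 1]` (`lat0`, `lon0`); the y index increases
#' northward and the x index eastward, with positions mapped through a local
#' equirectangular approximation (adequate over the few-hundred-km domains
#' simulated here).
#'
#' @param conc numeric array `[n_y, n_x, n_days]` of concentrations in
#'   percent; `NA` marks missing cells.
#' @param dates `Date` vector of length `n_days`, contiguous and increasing.
#' @param cell_km cell size in km (default 12.5).
#' @param lat0,lon0 latitude/longitude of the centre of cell `[1, 1]`.
#'
#' @return An object of class `ice_field`.
#' @export
ice_field <- function(conc, dates, cell_km = 12.5, lat0 = 76, lon0 = 10) {
  if (length(dim(conc)) != 3L) stop("`conc` must be a 3-d array [y, x, day]")
  dates <- as.Date(dates)
  if (dim(conc)[3] != length(dates)) {
    stop("third dimension of `conc` must match length(dates)")
  }
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L)) {
    stop("`dates` must be a contiguous daily sequence")
  }
  rng <- range(conc, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 100)) {
    stop("concentration values must lie in [0, 100]")
  }
  stopifnot_scalar_number(cell_km, "cell_km", positive = TRUE)
  structure(
    list(conc = conc, dates = dates, cell_km = cell_km,
         lat0 = lat0, lon0 = lon0),
    class = "ice_field"
  )
}

#' @export
print.ice_field <- function(x, ...) {
  d <- dim(x$conc)
  cat(sprintf(
    "<ice_field> %d x %d cells of %.1f km, %d days (%s to %s)\n",
    d[1], d[2], x$cell_km, d[3], min(x$dates), max(x$dates)))
  cat(sprintf("  origin cell centre: %.2fN %.2fE; mean conc %.1f%%\n",
              x$lat0, x$lon0, mean(x$conc, na.rm = TRUE)))
  invisible(x)
}

# Map lat/lon to fractional grid indices (1-based, cell centres at integers).
ice_grid_index <- function(ice, lat, lon) {
  y <- (lat - ice$lat0) * KM_PER_DEG / ice$cell_km + 1
  x <- (lon - ice$lon0) * KM_PER_DEG * cos(ice$lat0 * pi / 180) / ice$cell_km + 1
  list(iy = round(y), ix = round(x))
}

# Inverse mapping used by the simulator: latitude of row iy, etc.
ice_cell_lat <- function(ice, iy) ice$lat0 + (iy - 1) * ice$cell_km / KM_PER_DEG
ice_cell_lon <- function(ice, ix) {
  ice$lon0 + (ix - 1) * ice$cell_km / (KM_PER_DEG * cos(ice$lat0 * pi / 180))
}

#' Simulate a seasonal sea-ice concentration field
#'
#' Generates a daily ice-concentration grid with the qualitative seasonal
#' cycle of the Barents Sea region: maximum extent in April, minimum in
#' September, more ice to the north, with smooth spatial texture and
#' day-to-day persistence. Values are percent cover in `[0, 100]`.
#'
#' The concentration surface is an inverse-logit of a seasonal cosine
#' (peaking on day-of-year 105, mid-April), a south--north gradient, a
#' smoothed cell-level noise field and an AR1 daily offset; this is a
#' plausibility-level emulator, not a sea-ice physics model.
#'
#' @param seed integer seed; identical seeds give identical fields.
#' @param n_days number of daily grids (>= 1).
#' @param extent_km side length of the square domain in km.
#' @param start_date first date of the series.
#' @param cell_km grid cell size in km.
#' @param lat0,lon0 grid origin (centre of the south-west cell).
#' @param missing_frac fraction of cells set permanently missing (e.g.
#'   land-masked), default 0.
#'
#' @return An [ice_field].
#' @export
simulate_ice_field <- function(seed, n_days, extent_km = 500,
                               start_date = as.Date("2015-01-01"),
                               cell_km = 12.5, lat0 = 76, lon0 = 10,
                               missing_frac = 0) {
  stopifnot_scalar_number(n_days, "n_days", positive = TRUE)
  stopifnot_scalar_number(extent_km, "extent_km", positive = TRUE)
  n <- max(2L, as.integer(ceiling(extent_km / cell_km)))
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))

  with_seed(child_seed(seed, "ice_field"), {
    # static spatial texture, lightly smoothed
    noise <- matrix(stats::rnorm(n * n, 0, 0.9), n, n)
    sm <- noise
    if (n >= 3L) {
      core <- noise[2:(n - 1), 2:(n - 1)]
      sm[2:(n - 1), 2:(n - 1)] <-
        (core +
           noise[1:(n - 2), 2:(n - 1)] + noise[3:n, 2:(n - 1)] +
           noise[2:(n - 1), 1:(n - 2)] + noise[2:(n - 1), 3:n]) / 5
    }
    north <- matrix(rep(seq(-1.2, 1.2, length.out = n), n), n, n)
    season <- 1.8 * cos(2 * pi * (doy - 105) / 365.25)
    drift <- stats::filter(stats::rnorm(n_days, 0, 0.25), 0.9,
                           method = "recursive")
    conc <- array(NA_real_, c(n, n, n_days))
    for (d in seq_len(n_days)) {
      conc[, , d] <- 100 * stats::plogis(season[d] + north + sm + drift[d])
    }
    if (missing_frac > 0) {
      mask <- matrix(stats::runif(n * n) < missing_frac, n, n)
      conc[rep(mask, n_days)] <- NA_real_
    }
    ice_field(conc, dates, cell_km = cell_km, lat0 = lat0, lon0 = lon0)
  })
}

#' Extract sea-ice concentration at locations
#'
#' Looks up, for each location/date pair, the concentration of the grid cell
#' containing the point on that date (nearest-cell assignment, no
#' interpolation: concentration is an area product at 12.5-km scale).
#' Missing cells propagate as `NA`; points outside the spatial domain are
#' `NA`; dates outside the field's coverage are an error.
#'
#' @param lat,lon numeric vectors of coordinates (degrees, WGS84).
#' @param date `Date` (or coercible) vector, recycled if length 1.
#' @param ice an [ice_field].
#'
#' @return Numeric vector of concentrations in percent, `NA` where missing.
#' @export
extract_ice <- function(lat, lon, date, ice) {
  stopifnot(inherits(ice, "ice_field"))
  check_latlon(lat, lon)
  date <- as.Date(date)
  if (length(date) == 1L) date <- rep(date, length(lat))
  id <- match(date, ice$dates)
  if (anyNA(id)) {
    stop(sprintf("date %s outside ice coverage (%s to %s)",
                 date[which(is.na(id))[1]], min(ice$dates), max(ice$dates)),
         call. = FALSE)
  }
  gi <- ice_grid_index(ice, lat, lon)
  d <- dim(ice$conc)
  inside <- gi$iy >= 1 & gi$iy <= d[1] & gi$ix >= 1 & gi$ix <= d[2]
  out <- rep(NA_real_, length(lat))
  idx <- cbind(gi$iy[inside], gi$ix[inside], id[inside])
  out[inside] <- ice$conc[idx]
  out
}

#' Write / read an ice field as plain text
#'
#' Serializes an [ice_field] to a long-format CSV (`date, iy, ix, conc_pct`,
#' missing cells omitted) plus a JSON sidecar (`<prefix>.json`) holding the
#' grid metadata, and reads it back. Concentrations are stored to 4 decimal
#' places, so a round trip reproduces the field to that precision.
#'
#' @param ice an [ice_field].
#' @param prefix path prefix; files `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return `write_ice()` returns `prefix` invisibly; `read_ice()` returns an
#'   [ice_field].
#' @export
write_ice <- function(ice, prefix) {
  stopifnot(inherits(ice, "ice_field"))
  d <- dim(ice$conc)
  grid <- expand.grid(iy = seq_len(d[1]), ix = seq_len(d[2]),
                      day = seq_len(d[3]))
  v <- as.vector(ice$conc)
  keep <- !is.na(v)
  df <- data.frame(date = format(ice$dates[grid$day[keep]]),
                   iy = grid$iy[keep], ix = grid$ix[keep],
                   conc_pct = round(v[keep], 4))
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- list(n_y = d[1], n_x = d[2], cell_km = ice$cell_km,
               lat0 = ice$lat0, lon0 = ice$lon0,
               dates = format(ice$dates))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_ice
#' @export
read_ice <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, ".csv"))
  dates <- as.Date(meta$dates)
  conc <- array(NA_real_, c(meta$n_y, meta$n_x, length(dates)))
  day <- match(as.Date(df$date), dates)
  conc[cbind(df$iy, df$ix, day)] <- df$conc_pct
  ice_field(conc, dates, cell_km = meta$cell_km,
            lat0 = meta$lat0, lon0 = meta$lon0)
}
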
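#' Attach sea-ice and distance-to-land covariates to a track
#'
#' Adds, per location: `ice_pct` (concentration of the containing grid cell
#' on the location's date), `dist_big_km` and `dist_other_km` (distance to
#' the nearest large / small island polygon), and `julian_day`.
#'
#' @param track tibble with `time`, `lat`, `lon`.
#' @param ice an [ice_field].
#' @param coast a [coastline] with both `"big"` and `"other"` polygons.
#' @return `track` with covariate columns added.
#' @export
attach_covariates <- function(track, ice, coast) {
  track$ice_pct <- extract_ice(track$lat, track$lon, utc_day(track$time), ice)
  track$dist_big_km <- distance_to_land(track$lat, track$lon, coast, "big")
  track$dist_other_km <- if (any(coast$classes == "other")) {
    distance_to_land(track$lat, track$lon, coast, "other")
  } else Inf
  track$julian_day <- julian_day(track$time)
  track
}

#' Offshore screening filters
#'
#' Restricts covariate-attached records to the offshore modelling subset:
#' sea-ice concentration strictly greater than `ice_min_pct`; at least
#' `big_min_km` from the large islands; at least `other_min_km` from small
#' islands; and dated within the seasonal window (1 March -- 13 August,
#' inclusive). Records with missing ice are excluded (the ice rule cannot
#' be verified). Per-rule exclusion counts are attached as the
#' `"exclusion_counts"` attribute; a record failing several rules is
#' counted under each.
#'
#' @param records tibble from [attach_covariates()] (columns `time`,
#'   `ice_pct`, `dist_big_km`, `dist_other_km`).
#' @param ice_min_pct strict lower bound on ice concentration (default 15).
#' @param big_min_km minimum distance to large islands (default 6.25, half
#'   an ice grid cell).
#' @param other_min_km minimum distance to small islands (default 1).
#' @param period_start,period_end month-day bounds `"MM-DD"` of the
#'   retained season (defaults 1 March and 13 August).
#' @return The passing subset (same columns), with attribute
#'   `"exclusion_counts"`.
#' @export
screen_offshore <- function(records, ice_min_pct = 15, big_min_km = 6.25,
                            other_min_km = 1, period_start = "03-01",
                            period_end = "08-13") {
  md <- function(x) {
    v <- as.integer(strsplit(x, "-")[[1]])
    v[1] * 100L + v[2]
  }
  rec_md <- as.integer(format(as_utc(records$time), "%m")) * 100L +
    as.integer(format(as_utc(records$time), "%d"))
  ok_ice <- !is.na(records$ice_pct) & records$ice_pct > ice_min_pct
  ok_big <- records$dist_big_km >= big_min_km
  ok_other <- records$dist_other_km >= other_min_km
  ok_date <- rec_md >= md(period_start) & rec_md <= md(period_end)
  passes <- ok_ice & ok_big & ok_other & ok_date
  out <- records[passes, , drop = FALSE]
  attr(out, "exclusion_counts") <- c(
    ice = sum(!ok_ice), big_islands = sum(!ok_big),
    other_islands = sum(!ok_other), season = sum(!ok_date),
    excluded = sum(!passes), retained = sum(passes))
  out
}
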
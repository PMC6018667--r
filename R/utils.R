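# Internal helpers shared across modules.

KM_PER_DEG <- 6371 * pi / 180  # meridian km per degree on the 6371-km sphere

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

check_latlon <- function(lat, lon) {
  ok <- is.finite(lat) & is.finite(lon) & lat >= -90 & lat <= 90 &
    lon > -180 & lon <= 180
  if (!all(ok)) {
    stop("invalid coordinates: lat must lie in [-90, 90], lon in (-180, 180]",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic child seed streams: derive a distinct 32-bit seed per label
# from one master seed, so stages drawing random numbers stay independent.
child_seed <- function(seed, label) {
  stopifnot_scalar_number(seed, "seed")
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

utc_day <- function(time) as.Date(time, tz = "UTC")

julian_day <- function(time) {
  as.integer(format(as_utc(time), "%j"))
}
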
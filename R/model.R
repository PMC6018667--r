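#' Build model responses from screened 2-hour records
#'
#' Expands the 2-h time-in-water proportion into the modelled responses:
#' the proportion itself (as wet minutes out of 120) and binary indicators
#' for being wet at all (`any`), and for at least 1, 10 and 60 minutes of
#' the window (`>=` at the threshold; "at all" is strictly `> 0`). Also
#' attaches the absolute 2-h window index `step` used by the AR1
#' correlation structure, so gaps in a bear's series appear as jumps.
#'
#' @param records tibble with `bear_id`, `time`, `tiw` (proportion in
#'   \[0, 1\]), `ice_pct`, `julian_day`.
#' @return Tibble ordered by bear and time, with `any`, `ge_1min`,
#'   `ge_10min`, `ge_60min` (0/1), `wet_min` (0--120) and `step` added.
#' @export
build_responses <- function(records) {
  need <- c("bear_id", "time", "tiw", "ice_pct", "julian_day")
  stopifnot(all(need %in% names(records)))
  if (any(records$tiw < 0 | records$tiw > 1, na.rm = TRUE)) {
    stop("tiw must lie in [0, 1]")
  }
  out <- records[!is.na(records$tiw) & !is.na(records$ice_pct), , drop = FALSE]
  out$any <- as.integer(out$tiw > 0)
  out$ge_1min <- as.integer(out$tiw >= 1 / 120)
  out$ge_10min <- as.integer(out$tiw >= 10 / 120)
  out$ge_60min <- as.integer(out$tiw >= 60 / 120)
  out$wet_min <- as.integer(round(out$tiw * 120))
  out$step <- as.integer(round(as.numeric(as_utc(out$time)) / 7200))
  dplyr::arrange(out, bear_id, time)
}

RESPONSE_COLS <- c(ANY = "any", GE_1MIN = "ge_1min", GE_10MIN = "ge_10min",
                   GE_60MIN = "ge_60min", PROP_TIW = "wet_min")

#' Fit the binomial swimming GAMM
#'
#' Fits a penalized-spline logistic model of a swimming response on
#' sea-ice concentration and Julian day:
#' `response ~ s(ice_pct, k) + s(julian_day, k)`, binomial family, with a
#' per-bear random intercept and first-order autoregressive (AR1) residual
#' correlation within each bear's time-ordered 2-h series. The
#' `PROP_TIW` response is modelled as binomial counts of wet minutes out
#' of 120. Fitting uses `mgcv::gamm()` (penalized quasi-likelihood via
#' `nlme`), which is deterministic given the data; the AR1 correlation is
#' `phi^gap` in window steps, so correlation effectively resets across
#' long gaps.
#'
#' The `"gam"` engine drops the AR1 structure and fits the bear intercept
#' as an `mgcv` random-effect smooth by REML — appropriate for simulation
#' studies on independent data (e.g. null calibration of the smooth tests)
#' where the PQL machinery would be needlessly slow.
#'
#' @param table tibble from [build_responses()].
#' @param response one of `"ANY"`, `"GE_1MIN"`, `"GE_10MIN"`,
#'   `"GE_60MIN"`, `"PROP_TIW"`.
#' @param k basis dimension per smooth (default 10).
#' @param engine `"gamm"` (random intercept + AR1, the full model) or
#'   `"gam"`.
#' @param niterPQL maximum PQL iterations for the `"gamm"` engine.
#' @return An object of class `swim_gamm`: list with `gam` (the fitted
#'   `mgcv` model), `lme` (for the `"gamm"` engine), `response`, `engine`,
#'   `edf` (named per smooth), `s_table` (smooth tests), `ar1_phi`,
#'   `re_sd` (random-intercept sd), `n`, `n_bears`, and the fitted
#'   covariate ranges.
#' @export
fit_swim_gamm <- function(table, response = "ANY", k = 10,
                          engine = c("gamm", "gam"), niterPQL = 20) {
  engine <- match.arg(engine)
  if (!response %in% names(RESPONSE_COLS)) {
    stop("unknown response: ", response)
  }
  col <- RESPONSE_COLS[[response]]
  stopifnot(col %in% names(table))
  d <- data.frame(y = table[[col]], ice_pct = table$ice_pct,
                  julian_day = table$julian_day,
                  bear_id = factor(table$bear_id), step = table$step)
  if (nlevels(d$bear_id) < 2L) {
    stop("need >= 2 bears: the per-bear random intercept is unidentifiable",
         call. = FALSE)
  }
  if (response == "PROP_TIW") {
    d$fail <- 120L - d$y
    fml_y <- quote(cbind(y, fail))
  } else {
    fml_y <- quote(y)
  }

  if (engine == "gamm") {
    fml <- stats::as.formula(sprintf(
      "%s ~ s(ice_pct, k = %d) + s(julian_day, k = %d)",
      deparse(fml_y), k, k))
    fit <- tryCatch(
      mgcv::gamm(fml, data = d, family = stats::binomial(),
                 random = list(bear_id = ~1),
                 correlation = nlme::corAR1(form = ~ step | bear_id),
                 niterPQL = niterPQL, verbosePQL = FALSE),
      error = function(e) {
        stop("GAMM failed to converge (", conditionMessage(e),
             "); consider engine = 'gam' or more data", call. = FALSE)
      })
    gam_part <- fit$gam
    phi <- tryCatch({
      cs <- fit$lme$modelStruct$corStruct
      as.numeric(stats::coef(cs, unconstrained = FALSE)[1])
    }, error = function(e) NA_real_)
    re_sd <- tryCatch({
      vc <- nlme::VarCorr(fit$lme)
      ints <- which(rownames(vc) == "(Intercept)")
      as.numeric(vc[ints[length(ints)], "StdDev"])
    }, error = function(e) NA_real_)
    lme_part <- fit$lme
  } else {
    fml <- stats::as.formula(sprintf(
      "%s ~ s(ice_pct, k = %d) + s(julian_day, k = %d) + s(bear_id, bs = 're')",
      deparse(fml_y), k, k))
    gam_part <- mgcv::gam(fml, data = d, family = stats::binomial(),
                          method = "REML")
    phi <- NA_real_
    re_sd <- tryCatch({
      vc <- NULL
      utils::capture.output(
        vc <- mgcv::gam.vcomp(gam_part, rescale = FALSE))
      as.numeric(vc["s(bear_id)", "std.dev"])
    }, error = function(e) NA_real_)
    lme_part <- NULL
  }
  sm <- summary(gam_part)
  st <- sm$s.table
  smooth_rows <- grep("ice_pct|julian_day", rownames(st))
  structure(
    list(gam = gam_part, lme = lme_part, response = response,
         engine = engine, edf = stats::setNames(st[smooth_rows, "edf"],
                                                rownames(st)[smooth_rows]),
         s_table = st, ar1_phi = phi, re_sd = re_sd,
         n = nrow(d), n_bears = nlevels(d$bear_id),
         ice_range = range(d$ice_pct), day_range = range(d$julian_day)),
    class = "swim_gamm")
}

#' @export
print.swim_gamm <- function(x, ...) {
  cat(sprintf("<swim_gamm> response %s (%s engine), n = %d from %d bears\n",
              x$response, x$engine, x$n, x$n_bears))
  cat(sprintf("  edf: %s\n", paste(sprintf("%s = %.2f", names(x$edf), x$edf),
                                   collapse = ", ")))
  cat(sprintf("  AR1 phi = %s, random-intercept sd = %s\n",
              format(round(x$ar1_phi, 3)), format(round(x$re_sd, 3))))
  invisible(x)
}

#' Population-level prediction curves over sea-ice concentration
#'
#' Predicts the response probability over an ice-concentration grid at
#' reference Julian days (defaults 61, 152, 225: 1 March, 1 June, 13
#' August), with 95% confidence intervals from the smooth's standard
#' errors on the link scale. Predictions are population-level: the bear
#' random intercept is set to zero. Grid points outside the fitted
#' covariate range are flagged `extrapolated`.
#'
#' @param fit a [fit_swim_gamm()] result.
#' @param ice_grid numeric vector of ice concentrations (percent);
#'   default 15--100.
#' @param days Julian days at which to predict.
#' @return Tibble: `response`, `ice_pct`, `julian_day`, `p`, `lo95`,
#'   `hi95`, `extrapolated`.
#' @export
predict_swim_curves <- function(fit, ice_grid = seq(15, 100, by = 1),
                                days = c(61, 152, 225)) {
  stopifnot(inherits(fit, "swim_gamm"))
  nd <- expand.grid(ice_pct = ice_grid, julian_day = days)
  nd$step <- 0L
  excl <- NULL
  if (fit$engine == "gam") {
    nd$bear_id <- factor(fit$gam$model$bear_id[1],
                         levels = levels(fit$gam$model$bear_id))
    excl <- "s(bear_id)"
  }
  pr <- mgcv::predict.gam(fit$gam, newdata = nd, type = "link",
                          se.fit = TRUE, exclude = excl,
                          newdata.guaranteed = TRUE)
  tibble::tibble(
    response = fit$response, ice_pct = nd$ice_pct,
    julian_day = nd$julian_day,
    p = as.numeric(stats::plogis(pr$fit)),
    lo95 = as.numeric(stats::plogis(pr$fit - 1.96 * pr$se.fit)),
    hi95 = as.numeric(stats::plogis(pr$fit + 1.96 * pr$se.fit)),
    extrapolated = nd$ice_pct < fit$ice_range[1] |
      nd$ice_pct > fit$ice_range[2] |
      nd$julian_day < fit$day_range[1] | nd$julian_day > fit$day_range[2])
}

#' Summary of a fitted swimming GAMM as a plain list
#'
#' Collects the quantities usually reported — per-smooth effective degrees
#' of freedom and p-values, AR1 coefficient, random-intercept sd, sample
#' sizes — in a JSON-serializable list.
#'
#' @param fit a [fit_swim_gamm()] result.
#' @return A named list.
#' @export
swim_gamm_summary <- function(fit) {
  stopifnot(inherits(fit, "swim_gamm"))
  st <- fit$s_table
  rows <- grep("ice_pct|julian_day", rownames(st))
  list(response = fit$response, engine = fit$engine, n = fit$n,
       n_bears = fit$n_bears,
       edf = as.list(stats::setNames(st[rows, "edf"], rownames(st)[rows])),
       p_value = as.list(stats::setNames(st[rows, "p-value"],
                                         rownames(st)[rows])),
       ar1_phi = fit$ar1_phi, random_intercept_sd = fit$re_sd)
}
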
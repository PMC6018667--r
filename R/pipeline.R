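#' Pipeline configuration
#'
#' Assembles (with validation) the configuration driving [run_pipeline()].
#' Defaults equal the study's stated values: 5-s / 12-s swim start rules,
#' 48-h interpolation cap, 2-h steps, ice > 15%, 6.25 km / 1 km island
#' buffers, 1 March -- 13 August season, 50-km offshore threshold, basis
#' dimension 10.
#'
#' @param seed master seed for the simulation stage.
#' @param n_bears,duration_days,start_date,frac_coy,frac_offshore cohort
#'   settings passed to [make_fixture_cohort()].
#' @param start_run_telonics,start_run_smru swim-detection start runs (s).
#' @param max_gap_h,step_h track interpolation settings (hours).
#' @param ice_min_pct,big_min_km,other_min_km,period_start,period_end
#'   offshore screening settings.
#' @param offshore_dist_km strategy-classification threshold (km).
#' @param min_days minimum days per bear-month.
#' @param min_trip_gap_h minimum track gap treated as a swimming trip.
#' @param model_k basis dimension per smooth.
#' @param model_response response fitted by the model stage.
#' @param run_model whether the model stage runs (it needs a reasonably
#'   sized cohort).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_bears = 3L, duration_days = 10L,
                            start_date = "2015-04-01",
                            frac_coy = 0.3, frac_offshore = 0.3,
                            start_run_telonics = 5L, start_run_smru = 12L,
                            max_gap_h = 48, step_h = 2,
                            ice_min_pct = 15, big_min_km = 6.25,
                            other_min_km = 1,
                            period_start = "03-01", period_end = "08-13",
                            offshore_dist_km = 50, min_days = 5L,
                            min_trip_gap_h = 4, model_k = 10L,
                            model_response = "ANY", run_model = FALSE) {
  cfg <- list(seed = as.integer(seed), n_bears = as.integer(n_bears),
              duration_days = as.integer(duration_days),
              start_date = as.character(start_date),
              frac_coy = frac_coy, frac_offshore = frac_offshore,
              start_run_telonics = as.integer(start_run_telonics),
              start_run_smru = as.integer(start_run_smru),
              max_gap_h = max_gap_h, step_h = step_h,
              ice_min_pct = ice_min_pct, big_min_km = big_min_km,
              other_min_km = other_min_km,
              period_start = period_start, period_end = period_end,
              offshore_dist_km = offshore_dist_km,
              min_days = as.integer(min_days),
              min_trip_gap_h = min_trip_gap_h,
              model_k = as.integer(model_k),
              model_response = model_response,
              run_model = isTRUE(run_model))
  num <- c("start_run_telonics", "start_run_smru", "step_h",
           "big_min_km", "other_min_km", "offshore_dist_km", "model_k")
  for (f in num) stopifnot_scalar_number(cfg[[f]], f, positive = TRUE)
  if (cfg$max_gap_h < 0) stop("max_gap_h must be >= 0")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 12), collapse = ","), ""), sep = "=",
    collapse = ";")
  # small deterministic polynomial hash; provenance only, not cryptographic
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> emulate -> tracks -> screen -> metrics
#' (-> model) on a synthetic cohort, writing every stage's outputs as
#' plain files under `out_dir` so each stage is independently inspectable:
#' cohort files (streams, tracks, ice, coast, metadata), per-bear swim
#' events and summary windows, interpolated tracks with 2-h time in water,
#' screened records, monthly means, prevalence, long swims, depth
#' histograms, and (optionally) the fitted model summary and prediction
#' curves, plus a provenance log. Deterministic given the config: a rerun
#' reproduces identical data files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage products
#'   (`cohort`, `swims`, `daily`, `bear_months`, `prevalence`,
#'   `long_swims`, `screened`, `model`, `predictions`, `paths`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- stage("simulate", make_fixture_cohort(
    config$n_bears, config$seed, dir = file.path(out_dir, "cohort"),
    duration_days = config$duration_days, start_date = config$start_date,
    frac_coy = config$frac_coy, frac_offshore = config$frac_offshore))

  emu_dir <- file.path(out_dir, "emulated")
  dir.create(emu_dir, showWarnings = FALSE)
  daily_all <- list(); swims_all <- list(); tel_hours <- list()
  stage("emulate", for (d in cohort$deployments) {
    span <- c(d$start, d$end)
    if (d$tag_type == "TDR") {
      hourly <- hourly_pct_wet_tdr(d$stream)
      utils::write.csv(
        data.frame(window_start_utc = format(hourly$window_start, TS_FMT),
                   window_h = hourly$window_h,
                   pct_wet = sprintf("%.4f", hourly$pct_wet)),
        file.path(emu_dir, paste0(d$bear_id, "_hourly.csv")),
        row.names = FALSE, quote = FALSE)
      dd <- daily_tiw_tdr(d$stream)
    } else {
      run <- if (d$tag_type == "TELONICS") config$start_run_telonics else
        config$start_run_smru
      wet <- d$stream$conductivity == 1
      swims <- detect_swims(wet, run, t0 = d$stream$time[1],
                            depth = if (d$tag_type == "SMRU")
                              d$stream$depth_m else NULL)
      utils::write.csv(
        data.frame(start_utc = format(swims$start, TS_FMT),
                   duration_s = swims$duration_s,
                   max_depth_m = ifelse(is.na(swims$max_depth_m), "",
                                        sprintf("%.2f", swims$max_depth_m))),
        file.path(emu_dir, paste0(d$bear_id, "_swims.csv")),
        row.names = FALSE, quote = FALSE)
      swims_all[[d$bear_id]] <- swims
      if (d$tag_type == "TELONICS") {
        tel_hours[[d$bear_id]] <- hourly_pct_wet_telonics(swims, span = span)
      } else {
        w4 <- summarize_windows_smru(swims, depth = d$stream$depth_m,
                                     t0 = d$stream$time[1], span = span)
        utils::write.csv(
          data.frame(window_start_utc = format(w4$window_start, TS_FMT),
                     window_h = w4$window_h,
                     pct_wet = sprintf("%.4f", w4$pct_wet)),
          file.path(emu_dir, paste0(d$bear_id, "_4h.csv")),
          row.names = FALSE, quote = FALSE)
      }
      dd <- daily_tiw_swims(swims, span)
    }
    dd$bear_id <- d$bear_id
    dd$reproductive_status <- d$reproductive_status
    daily_all[[d$bear_id]] <- dd
  })
  daily <- dplyr::bind_rows(daily_all)

  trk_dir <- file.path(out_dir, "tracks")
  dir.create(trk_dir, showWarnings = FALSE)
  screened_all <- list(); long_all <- list()
  stage("tracks", for (d in cohort$deployments) {
    itrk <- interpolate_track(d$track, config$max_gap_h, config$step_h)
    itrk <- attach_time_in_water(
      itrk, telonics_hours = tel_hours[[d$bear_id]],
      tdr_stream = if (d$tag_type == "TDR") d$stream else NULL)
    utils::write.csv(
      data.frame(timestamp_utc = format(itrk$time, TS_FMT),
                 lat = sprintf("%.6f", itrk$lat),
                 lon = sprintf("%.6f", itrk$lon),
                 interpolated = as.integer(itrk$interpolated),
                 tiw_2h = ifelse(is.na(itrk$tiw_2h), "",
                                 sprintf("%.6f", itrk$tiw_2h))),
      file.path(trk_dir, paste0(d$bear_id, "_track.csv")),
      row.names = FALSE, quote = FALSE)
    cov <- attach_covariates(itrk, cohort$ice, cohort$coast)
    cov$bear_id <- d$bear_id
    screened_all[[d$bear_id]] <- cov
    if (!is.null(swims_all[[d$bear_id]])) {
      trips <- find_gap_trips(d$track, config$min_trip_gap_h)
      if (nrow(trips) && config$max_gap_h > 0) {
        trips <- trips[trips$gap_h < config$max_gap_h, , drop = FALSE]
        if (nrow(trips)) {
          ls <- dplyr::bind_rows(lapply(seq_len(nrow(trips)), function(i)
            summarize_long_swim(trips[i, ], swims_all[[d$bear_id]])))
          ls$bear_id <- d$bear_id
          long_all[[d$bear_id]] <- ls
        }
      }
    }
  })
  long_swims <- dplyr::bind_rows(long_all)
  if (nrow(long_swims) == 0L) {
    long_swims <- tibble::tibble(start = as_utc(character(0)),
                                 end = as_utc(character(0)),
                                 distance_km = numeric(0),
                                 trip_hours = numeric(0),
                                 swim_hours = numeric(0),
                                 max_continuous_hours = numeric(0),
                                 bear_id = character(0))
  }
  write_long_swims(long_swims, file.path(out_dir, "long_swims.csv"))

  screened <- stage("screen", {
    all_cov <- dplyr::bind_rows(screened_all)
    sc <- screen_offshore(all_cov, config$ice_min_pct, config$big_min_km,
                          config$other_min_km, config$period_start,
                          config$period_end)
    utils::write.csv(
      data.frame(bear_id = sc$bear_id,
                 timestamp_utc = format(sc$time, TS_FMT),
                 lat = sprintf("%.6f", sc$lat), lon = sprintf("%.6f", sc$lon),
                 ice_pct = sprintf("%.4f", sc$ice_pct),
                 dist_big_km = sprintf("%.3f", sc$dist_big_km),
                 dist_other_km = sprintf("%.3f", sc$dist_other_km),
                 julian_day = sc$julian_day,
                 tiw_2h = ifelse(is.na(sc$tiw_2h), "",
                                 sprintf("%.6f", sc$tiw_2h))),
      file.path(out_dir, "screened.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.list(attr(sc, "exclusion_counts")),
                         file.path(out_dir, "screening_log.json"),
                         auto_unbox = TRUE)
    sc
  })

  res <- stage("metrics", {
    bm <- monthly_means(daily, config$min_days)
    utils::write.csv(
      data.frame(bear_id = bm$bear_id, year_month = bm$year_month,
                 month = bm$month,
                 mean_pct_tiw = sprintf("%.4f", bm$mean_pct_tiw),
                 n_days = bm$n_days,
                 reproductive_status = bm$reproductive_status),
      file.path(out_dir, "monthly_means.csv"), row.names = FALSE,
      quote = FALSE)
    prev <- dplyr::bind_rows(lapply(c("day", "week", "month"),
                                    function(p) swim_prevalence(daily, p)))
    utils::write.csv(
      data.frame(period = prev$period, month = prev$month,
                 prevalence = sprintf("%.4f", prev$prevalence),
                 n_units = prev$n_units),
      file.path(out_dir, "prevalence.csv"), row.names = FALSE, quote = FALSE)
    list(bear_months = bm, prevalence = prev)
  })

  model <- NULL; predictions <- NULL
  if (config$run_model) {
    model <- stage("model", {
      tab <- build_responses(dplyr::rename(screened, tiw = tiw_2h))
      fit <- fit_swim_gamm(tab, config$model_response, k = config$model_k)
      jsonlite::write_json(swim_gamm_summary(fit),
                           file.path(out_dir, "model_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      fit
    })
    predictions <- predict_swim_curves(model)
    utils::write.csv(
      data.frame(response = predictions$response,
                 ice_pct = predictions$ice_pct,
                 julian_day = predictions$julian_day,
                 p = sprintf("%.6f", predictions$p),
                 lo95 = sprintf("%.6f", predictions$lo95),
                 hi95 = sprintf("%.6f", predictions$hi95)),
      file.path(out_dir, "predictions.csv"), row.names = FALSE,
      quote = FALSE)
  }

  prov <- list(package = "bearswim",
               version = as.character(utils::packageVersion("bearswim")),
               config = unclass(config), config_hash = config_hash(config),
               stages = c("simulate", "emulate", "tracks", "screen",
                          "metrics", if (config$run_model) "model"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, swims = swims_all, daily = daily,
                 bear_months = res$bear_months, prevalence = res$prevalence,
                 long_swims = long_swims, screened = screened,
                 model = model, predictions = predictions,
                 paths = list(out_dir = out_dir)))
}

write_long_swims <- function(ls, path) {
  utils::write.csv(
    data.frame(bear_id = ls$bear_id, start_utc = format(ls$start, TS_FMT),
               end_utc = format(ls$end, TS_FMT),
               distance_km = sprintf("%.2f", ls$distance_km),
               trip_hours = sprintf("%.2f", ls$trip_hours),
               swim_hours = sprintf("%.2f", ls$swim_hours),
               max_continuous_hours = sprintf("%.2f", ls$max_continuous_hours)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabular report from pipeline artifacts
#'
#' Reads a [run_pipeline()] output directory back into the summary tables
#' a study report would show: monthly means per bear, swim prevalence by
#' period and month, the long-swim table, the depth histogram of daily
#' maxima (from SMRU swim files), and prediction curves when the model
#' stage ran. Purely a re-reader: values equal the stage outputs exactly.
#'
#' @param dir a [run_pipeline()] output directory.
#' @return A list of tibbles: `monthly_means`, `prevalence`, `long_swims`,
#'   `depth_histogram`, `predictions` (`NULL` if the model stage did not
#'   run).
#' @export
make_report <- function(dir) {
  need <- file.path(dir, c("monthly_means.csv", "prevalence.csv",
                           "long_swims.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing pipeline artifacts: ",
                         paste(basename(miss), collapse = ", "))
  mm <- tibble::as_tibble(utils::read.csv(need[1]))
  prev <- tibble::as_tibble(utils::read.csv(need[2]))
  ls <- tibble::as_tibble(utils::read.csv(need[3]))
  swim_files <- list.files(file.path(dir, "emulated"), "_swims\\.csv$",
                           full.names = TRUE)
  depths <- dplyr::bind_rows(lapply(swim_files, function(f) {
    sw <- utils::read.csv(f)
    sw <- sw[!is.na(sw$max_depth_m), , drop = FALSE]
    if (nrow(sw) == 0L) return(NULL)
    dm <- daily_max_depth(tibble::tibble(start = as_utc(sw$start_utc),
                                         duration_s = sw$duration_s,
                                         max_depth_m = sw$max_depth_m))
    dm$bear_id <- sub("_swims\\.csv$", "", basename(f))
    dm
  }))
  hist <- if (nrow(depths) == 0L) depth_histogram(
    tibble::tibble(max_depth_m = numeric(0))) else depth_histogram(depths)
  pred_file <- file.path(dir, "predictions.csv")
  preds <- if (file.exists(pred_file)) {
    tibble::as_tibble(utils::read.csv(pred_file))
  } else NULL
  list(monthly_means = mm, prevalence = prev, long_swims = ls,
       depth_histogram = hist, predictions = preds)
}
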
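# End-to-end pipeline: development fits (optional), biofix grid search,
# final flight fit, year-split validation, median-flight extraction, and
# life-stage forecasts.

#' Pipeline configuration
#'
#' Assembles and validates the settings for [run_pipeline()]. Inputs may be
#' file paths (read with the package's CSV readers) or data frames.
#'
#' @param weather Daily weather: path or data frame (see [read_weather_csv()]).
#' @param traps Trap counts: path or data frame (see [read_trap_csv()]).
#' @param development Optional rearing records: path or data frame.
#' @param ldt Lower developmental threshold (degrees C). If `NULL` and rearing
#'   records are supplied, the pooled threshold across stage-by-diet fits is
#'   used; otherwise defaults to 9.8.
#' @param method Degree-day method for the final model when the grid search is
#'   disabled, and the preferred method among grid winners otherwise.
#' @param start_doy Accumulation start day-of-year when the grid search is
#'   disabled. Default 120.
#' @param grid_search Run the biofix grid search? Default `TRUE`.
#' @param doy_grid,methods Grid-search settings (see [grid_search_biofix()]).
#' @param fix_delta,var_covariate Flight-model settings (see
#'   [fit_logistic_gls()]).
#' @param min_total Seasonal-total filter.
#' @param cv_train_frac Fraction of years used for training in validation.
#' @param forecast_preset Stage-threshold preset for forecasts (see
#'   [stage_thresholds()]), or `NA` to skip forecasting.
#' @param seed Master seed for the year split and bootstrap intervals.
#' @param out_dir Optional output directory for JSON/CSV reports.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(weather, traps, development = NULL,
                            ldt = NULL, method = "single_sine",
                            start_doy = 120L, grid_search = TRUE,
                            doy_grid = seq(5L, 125L, by = 5L),
                            methods = dd_methods,
                            fix_delta = NULL, var_covariate = "year",
                            min_total = 20, cv_train_frac = 0.5,
                            forecast_preset = "combined",
                            seed = 1L, out_dir = NULL) {
  if (is.null(weather) || is.null(traps)) {
    stop("pipeline configuration requires both weather and traps inputs", call. = FALSE)
  }
  for (p in list(weather, traps, development)) {
    if (is.character(p) && !file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  structure(list(weather = weather, traps = traps, development = development,
                 ldt = ldt, method = match.arg(method, dd_methods),
                 start_doy = as.integer(start_doy),
                 grid_search = isTRUE(grid_search),
                 doy_grid = doy_grid, methods = methods,
                 fix_delta = fix_delta, var_covariate = var_covariate,
                 min_total = min_total, cv_train_frac = cv_train_frac,
                 forecast_preset = forecast_preset,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x)) reader(x) else x
}

#' Run the full phenology pipeline
#'
#' Executes, in order: development-rate fits and threshold pooling (when
#' rearing data are supplied), the biofix grid search (or a single configured
#' candidate), the final heteroskedastic logistic fit, year-split
#' cross-validation, median-flight extraction with a bootstrap interval, and
#' per-site-year life-stage forecasts using the predicted median flight date
#' as the biofix. When `out_dir` is set, writes `results.json`,
#' `candidate_scores.csv` and `forecasts.csv`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"pipeline_result"` with elements `development`,
#'   `ldt`, `search`, `selected`, `fit`, `score`, `cv`, `median_flight`,
#'   `forecasts`, and `meta` (seed and package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  weather <- resolve_input(config$weather, read_weather_csv)
  traps <- resolve_input(config$traps, read_trap_csv)

  # -- development stage ------------------------------------------------------
  development <- NULL
  ldt <- config$ldt
  if (!is.null(config$development)) {
    dev <- resolve_input(config$development, read_development_csv)
    fits <- fit_development(dev)
    combined <- fits[grepl("\\.combined$", names(fits))]
    if (length(combined) == 0L) combined <- fits
    pool <- pooled_ldt(combined)
    if (is.null(ldt)) ldt <- pool$t
    fixed <- lapply(split(dev[dev$completed, , drop = FALSE],
                          list(dev$stage[dev$completed], dev$diet[dev$completed]),
                          drop = TRUE),
                    thermal_constant_fixed_ldt, ldt = ldt)
    development <- list(
      fits = lapply(fits, function(f) f[c("stage", "diet", "a", "b", "se_b",
                                          "t", "se_t", "k", "se_k", "n", "status")]),
      pooled_ldt = pool,
      fixed_ldt_requirements = lapply(fixed, function(x) x)
    )
  }
  if (is.null(ldt)) ldt <- 9.8

  # -- model selection --------------------------------------------------------
  search <- NULL
  if (config$grid_search) {
    search <- grid_search_biofix(traps, weather, ldt = ldt,
                                 doy_grid = config$doy_grid,
                                 methods = config$methods,
                                 min_total = config$min_total,
                                 fix_delta = config$fix_delta,
                                 var_covariate = config$var_covariate)
    pref <- search$best[search$best$method == config$method, , drop = FALSE]
    sel <- if (nrow(pref) == 1L) pref else search$best[1L, , drop = FALSE]
    selected <- list(method = sel$method, start_doy = sel$start_doy)
  } else {
    selected <- list(method = config$method, start_doy = config$start_doy)
  }

  # -- final fit, validation, median flight -----------------------------------
  params <- dd_params(selected$method, ldt = ldt, start_doy = selected$start_doy)
  gdd <- accumulate_gdd(weather, params)
  catch <- cumulative_catch(traps, gdd, min_total = config$min_total)
  fit <- fit_logistic_gls(catch, fix_delta = config$fix_delta,
                          var_covariate = config$var_covariate)
  score <- score_candidate(catch, fit)
  cv <- if (length(unique(catch$year)) >= 2L) {
    year_split_cv(catch, train_frac = config$cv_train_frac, seed = config$seed,
                  fit_args = list(fix_delta = config$fix_delta,
                                  var_covariate = config$var_covariate))
  } else NULL
  med <- median_flight_gdd(fit, seed = config$seed)

  # -- forecasts from predicted median flight ---------------------------------
  forecasts <- NULL
  if (!is.na(config$forecast_preset)) {
    thr <- stage_thresholds(config$forecast_preset, ldt = ldt)
    rows <- list()
    for (sy in unique(catch$site_year_id)) {
      g <- gdd[gdd$site_year_id == sy, , drop = FALSE]
      i <- which(g$cumulative_gdd >= med$gdd)[1L]
      if (is.na(i)) next
      fc <- tryCatch(
        suppressWarnings(project_stage_windows(g$date[i], weather[weather$site_year_id == sy, ],
                                               thr, method = selected$method)),
        error = function(e) NULL)
      if (is.null(fc)) next
      rows[[sy]] <- data.frame(site_year_id = sy,
                               biofix_date = fc$biofix_date,
                               stage = fc$stages$stage,
                               checkpoint_gdd = fc$stages$checkpoint_gdd,
                               date = fc$stages$date,
                               days_after_biofix = fc$stages$days_after_biofix,
                               truncated = fc$truncated)
    }
    forecasts <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
    if (!is.null(forecasts)) rownames(forecasts) <- NULL
  }

  result <- structure(list(
    development = development,
    ldt = ldt,
    search = search,
    selected = selected,
    fit = fit,
    score = score,
    cv = cv,
    median_flight = med,
    forecasts = forecasts,
    meta = list(seed = config$seed,
                package_version = as.character(utils::packageVersion("phenoflight")))
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

pipeline_report <- function(result) {
  list(
    meta = result$meta,
    ldt = result$ldt,
    development = if (!is.null(result$development)) list(
      pooled_ldt = result$development$pooled_ldt,
      fixed_ldt_requirements = result$development$fixed_ldt_requirements
    ),
    selected = result$selected,
    flight_fit = result$fit[c("a", "b", "c", "sigma", "delta", "n", "convergence")],
    score = result$score,
    validation = if (!is.null(result$cv)) {
      unclass(result$cv)[c("train_years", "test_years", "slope", "intercept",
                           "rmse", "mae", "r2", "pseudo_r2", "n_test")]
    },
    median_flight = result$median_flight
  )
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_json(pipeline_report(result), file.path(out_dir, "results.json"))
  if (!is.null(result$search)) {
    sc <- result$search$scores
    sc[c("mae", "rmse", "pseudo_r2")] <- lapply(sc[c("mae", "rmse", "pseudo_r2")],
                                                signif, digits = 6)
    utils::write.csv(sc, file.path(out_dir, "candidate_scores.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$forecasts)) {
    fc <- result$forecasts
    fc$biofix_date <- format(fc$biofix_date, "%Y-%m-%d")
    fc$date <- format(fc$date, "%Y-%m-%d")
    fc$checkpoint_gdd <- signif(fc$checkpoint_gdd, 6)
    utils::write.csv(fc, file.path(out_dir, "forecasts.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Phenology pipeline result\n")
  cat(sprintf("  LDT used: %.2f degC\n", x$ldt))
  cat(sprintf("  selected model: %s, start DOY %d\n",
              x$selected$method, x$selected$start_doy))
  cat(sprintf("  flight fit: a = %.3f, b = %.1f, c = %.1f GDD\n",
              x$fit$a, x$fit$b, x$fit$c))
  cat(sprintf("  median flight: %.1f GDD (%.0f%% CI %.1f-%.1f)\n",
              x$median_flight$gdd, 100 * x$median_flight$level,
              x$median_flight$lower, x$median_flight$upper))
  if (!is.null(x$cv)) {
    cat(sprintf("  validation: RMSE %.3f, R2 %.3f, obs = %.3f + %.3f * pred\n",
                x$cv$rmse, x$cv$r2, x$cv$intercept, x$cv$slope))
  }
  invisible(x)
}
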
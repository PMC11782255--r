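# Candidate phenology model scoring, biofix grid search, and year-split
# cross-validation.

#' Pseudo coefficient of determination for nonlinear fits
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Equals 1 for a perfect fit
#' and 0 when the predictions do no better than the observed mean; can be
#' negative for fits worse than the mean.
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return A single number `<= 1`.
#' @export
pseudo_r2 <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("all observed values identical: pseudo-R2 undefined", call. = FALSE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Score a fitted flight model on its fitting data
#'
#' Mean absolute error, root mean squared error, and pseudo-R-squared of the
#' fitted cumulative proportions against the observed ones, pooled over all
#' site-year visit points.
#'
#' @param data Data frame from [cumulative_catch()].
#' @param fit A `"logistic_flight_fit"` for those data.
#' @return List with `mae`, `rmse`, `pseudo_r2`, `n`.
#' @export
score_candidate <- function(data, fit) {
  yhat <- predict_cumulative(fit, data$gdd)
  r <- data$prop - yhat
  list(mae = mean(abs(r)),
       rmse = sqrt(mean(r^2)),
       pseudo_r2 = pseudo_r2(data$prop, yhat),
       n = length(r))
}

# Fast inner loop shared by grid_search_biofix: daily degree days per method
# are computed once over the weather table, and each candidate start day only
# changes the mask before the running sum.
grid_gdd_at_visits <- function(dd_all, doy, sy_index, start_doy, hit) {
  dd <- dd_all
  dd[doy < start_doy] <- 0
  cum <- stats::ave(dd, sy_index, FUN = cumsum)
  cum[hit]
}

#' Grid search for the degree-day accumulation start date
#'
#' Fits the logistic flight model for every combination of degree-day
#' calculation method and candidate accumulation start day-of-year, scores
#' each candidate by MAE, RMSE and pseudo-R-squared on the fitting data, and
#' selects the best candidate per method (lowest MAE, ties broken by lower
#' RMSE, then by earlier start day). The default grid spans early January
#' through 5 May in five-day steps, 25 start days by 3 methods = 75 candidate
#' models. A candidate whose fit fails is recorded with `NA` scores rather
#' than aborting the search.
#'
#' @param traps Trap-count data frame (see [cumulative_catch()]).
#' @param weather Daily weather data frame (see [accumulate_gdd()]).
#' @param ldt Lower developmental threshold (degrees C).
#' @param doy_grid Candidate start days of year. Default `seq(5, 125, by = 5)`.
#' @param methods Degree-day methods to evaluate; default all three.
#' @param udt Optional upper threshold passed to the degree-day calculation.
#' @param min_total Seasonal-total filter (see [cumulative_catch()]).
#' @param fix_delta,var_covariate Passed to [fit_logistic_gls()].
#' @return An object of class `"biofix_search"`: list with `scores` (one row
#'   per candidate: `method`, `start_doy`, `mae`, `rmse`, `pseudo_r2`,
#'   `converged`), `best` (one row per method plus the overall winner first),
#'   and `best_fits` (named list of refitted winning models per method, with
#'   covariance).
#' @export
grid_search_biofix <- function(traps, weather, ldt,
                               doy_grid = seq(5L, 125L, by = 5L),
                               methods = dd_methods, udt = NULL,
                               min_total = 20, fix_delta = NULL,
                               var_covariate = "year") {
  stopifnot(all(doy_grid >= 1L), all(doy_grid <= 366L))
  check_weather(weather)
  weather <- weather[order(weather$site_year_id, weather$date), , drop = FALSE]
  doy <- as.integer(format(weather$date, "%j"))
  sy_index <- match(weather$site_year_id, unique(weather$site_year_id))

  # proportions and the visit->weather row map do not depend on the candidate
  base_gdd <- accumulate_gdd(weather, dd_params(methods[1L], ldt = ldt, start_doy = 1L))
  catch <- cumulative_catch(traps, base_gdd, min_total = min_total)
  traps_kept <- traps[order(traps$site_year_id, traps$visit_date), , drop = FALSE]
  traps_kept <- traps_kept[paste(traps_kept$site_year_id) %in% unique(catch$site_year_id), , drop = FALSE]
  hit <- match(paste(traps_kept$site_year_id, format(traps_kept$visit_date)),
               paste(weather$site_year_id, format(weather$date)))

  rows <- vector("list", length(methods) * length(doy_grid))
  i <- 0L
  for (m in methods) {
    dd_all <- dd_one_method(weather$tmin, weather$tmax, ldt, udt, m)
    for (d0 in doy_grid) {
      i <- i + 1L
      dat <- catch
      dat$gdd <- grid_gdd_at_visits(dd_all, doy, sy_index, d0, hit)
      res <- tryCatch({
        fit <- fit_logistic_gls(dat, fix_delta = fix_delta,
                                var_covariate = var_covariate,
                                compute_cov = FALSE)
        sc <- score_candidate(dat, fit)
        data.frame(method = m, start_doy = d0, mae = sc$mae, rmse = sc$rmse,
                   pseudo_r2 = sc$pseudo_r2, converged = fit$convergence == 0)
      }, error = function(e) {
        data.frame(method = m, start_doy = d0, mae = NA_real_, rmse = NA_real_,
                   pseudo_r2 = NA_real_, converged = FALSE)
      })
      rows[[i]] <- res
    }
  }
  scores <- do.call(rbind, rows)
  usable <- scores[!is.na(scores$mae), , drop = FALSE]
  if (nrow(usable) == 0L) stop("every candidate model failed to fit", call. = FALSE)

  pick_best <- function(df) {
    df <- df[order(df$mae, df$rmse, df$start_doy), , drop = FALSE]
    df[1L, , drop = FALSE]
  }
  best <- do.call(rbind, lapply(split(usable, usable$method), pick_best))
  best <- best[order(best$mae, best$rmse, best$start_doy), , drop = FALSE]
  rownames(best) <- NULL

  best_fits <- list()
  for (j in seq_len(nrow(best))) {
    m <- best$method[j]; d0 <- best$start_doy[j]
    g <- accumulate_gdd(weather, dd_params(m, ldt = ldt, udt = udt, start_doy = d0))
    dat <- suppressMessages(cumulative_catch(traps, g, min_total = min_total))
    best_fits[[m]] <- tryCatch(
      fit_logistic_gls(dat, fix_delta = fix_delta, var_covariate = var_covariate),
      error = function(e) NULL)
  }

  structure(list(scores = scores, best = best, best_fits = best_fits,
                 ldt = ldt, doy_grid = doy_grid, methods = methods),
            class = "biofix_search")
}

#' @export
print.biofix_search <- function(x, ...) {
  cat(sprintf("Biofix grid search: %d candidates (%d methods x %d start days), LDT %.2f degC\n",
              nrow(x$scores), length(x$methods), length(x$doy_grid), x$ldt))
  cat("Best per method:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Year-split cross-validation of the flight model
#'
#' Splits the site-years by calendar year into train and test sets, fits the
#' logistic flight model on the training years, predicts the test-year
#' cumulative proportions at their observed degree-day values, and regresses
#' observed on predicted values. A well-calibrated model gives slope near 1
#' and intercept near 0.
#'
#' @param data Data frame from [cumulative_catch()].
#' @param train_frac Fraction of years assigned to training (default 0.5).
#' @param seed Optional seed for the random year split.
#' @param train_years,test_years Explicit year sets overriding the random
#'   split (both must be given together; they may overlap only if identical,
#'   which reproduces in-sample scores).
#' @param direction `"obs_on_pred"` (default) regresses observed on predicted;
#'   `"pred_on_obs"` the reverse.
#' @param fit_args List of extra arguments for [fit_logistic_gls()].
#' @return An object of class `"phenology_cv"`: `train_years`, `test_years`,
#'   `slope`, `intercept`, `rmse`, `mae`, `r2` (of the validation regression),
#'   `pseudo_r2`, `n_test`, and the training `fit`.
#' @export
year_split_cv <- function(data, train_frac = 0.5, seed = NULL,
                          train_years = NULL, test_years = NULL,
                          direction = c("obs_on_pred", "pred_on_obs"),
                          fit_args = list()) {
  direction <- match.arg(direction)
  years <- sort(unique(data$year))
  if (is.null(train_years) != is.null(test_years)) {
    stop("supply both train_years and test_years, or neither", call. = FALSE)
  }
  if (is.null(train_years)) {
    if (length(years) < 2L) stop("need >= 2 distinct years to split", call. = FALSE)
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(seed)
    }
    n_train <- max(1L, min(length(years) - 1L, round(train_frac * length(years))))
    train_years <- sort(sample(years, n_train))
    test_years <- setdiff(years, train_years)
  } else {
    if (!setequal(train_years, test_years) &&
        length(intersect(train_years, test_years)) > 0L) {
      stop("train and test years must be disjoint (or identical for an in-sample check)",
           call. = FALSE)
    }
  }
  train <- data[data$year %in% train_years, , drop = FALSE]
  test <- data[data$year %in% test_years, , drop = FALSE]
  if (nrow(train) == 0L) stop("no site-years in the training years", call. = FALSE)
  if (nrow(test) == 0L) stop("no site-years in the test years", call. = FALSE)

  fit <- do.call(fit_logistic_gls, c(list(data = train), fit_args))
  pred <- predict_cumulative(fit, test$gdd)
  obs <- test$prop
  reg <- if (direction == "obs_on_pred") stats::lm(obs ~ pred) else stats::lm(pred ~ obs)
  co <- stats::coef(reg)

  structure(list(
    train_years = sort(unique(train$year)),
    test_years = sort(unique(test$year)),
    slope = unname(co[2L]),
    intercept = unname(co[1L]),
    rmse = sqrt(mean((obs - pred)^2)),
    mae = mean(abs(obs - pred)),
    r2 = summary(reg)$r.squared,
    pseudo_r2 = pseudo_r2(obs, pred),
    direction = direction,
    n_test = length(obs),
    fit = fit
  ), class = "phenology_cv")
}

#' @export
print.phenology_cv <- function(x, ...) {
  cat(sprintf("Year-split validation: %d train / %d test years, %d test points\n",
              length(x$train_years), length(x$test_years), x$n_test))
  cat(sprintf("  observed ~ predicted: y = %.3f + %.3f x\n", x$intercept, x$slope))
  cat(sprintf("  RMSE = %.3f, R2 = %.3f, pseudo-R2 = %.3f\n", x$rmse, x$r2, x$pseudo_r2))
  invisible(x)
}
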
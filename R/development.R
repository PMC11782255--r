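# Lower developmental thresholds and thermal constants from
# constant-temperature rearing data (Campbell rate-regression method).
#
# Development rate y = 1/days is regressed on rearing temperature T per
# specimen: y = a + b*T. The lower threshold is t = -a/b (rate extrapolates to
# zero) and the thermal constant is k = 1/b degree days. Standard errors follow
# the classical formulas:
#   SE(t) = (ybar/b) * sqrt( s^2/(N*ybar^2) + (SE(b)/b)^2 )
#   SE(k) = SE(b)/b^2
# with s^2 the residual mean square of y and ybar the sample mean rate.

check_dev_obs <- function(observations) {
  need <- c("temperature", "days", "completed")
  miss <- setdiff(need, names(observations))
  if (length(miss) > 0L) {
    stop("development observations missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  done <- observations$completed
  if (any(done & (!is.finite(observations$days) | observations$days <= 0))) {
    stop("completed observations must have days > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a development-rate regression for one life stage
#'
#' Ordinary least squares of per-specimen development rate (1/days) on
#' constant rearing temperature, for the records of a single life stage (and
#' typically a single diet). Temperatures at which no specimen completed the
#' stage (complete mortality) are excluded automatically with a message, which
#' mirrors how sub-threshold rearing temperatures are handled in practice.
#' Returns the regression coefficients together with the derived lower
#' developmental threshold `t = -a/b`, thermal constant `k = 1/b`, and their
#' standard errors.
#'
#' @param observations Data frame with columns `temperature` (degrees C),
#'   `days` (duration to stage completion), `completed` (logical), and
#'   optionally `stage` and `diet` labels carried through to the result.
#' @return An object of class `"stage_thermal_fit"`: a list with elements
#'   `a`, `b`, `se_a`, `se_b`, `s2`, `n`, `ybar`, `t`, `se_t`, `k`, `se_k`,
#'   `stage`, `diet`, `excluded_temperatures`, and `status` (`"ok"` or
#'   `"nonphysical_slope"` when the fitted slope is not positive).
#' @examples
#' obs <- data.frame(temperature = rep(c(17, 22, 27, 32), each = 2))
#' obs$days <- 650 / (obs$temperature - 9.8)
#' obs$completed <- TRUE
#' fit_stage_rate(obs) # recovers t = 9.8, k = 650 exactly
#' @export
fit_stage_rate <- function(observations) {
  check_dev_obs(observations)
  done <- observations[observations$completed, , drop = FALSE]
  if (nrow(done) == 0L) stop("no completed observations", call. = FALSE)

  # exclude temperatures with complete mortality
  all_temps <- unique(observations$temperature)
  kept_temps <- unique(done$temperature)
  dropped <- setdiff(all_temps, kept_temps)
  if (length(dropped) > 0L) {
    message("excluding temperature(s) with no completed specimens: ",
            paste(sort(dropped), collapse = ", "), " degC")
  }
  if (length(kept_temps) < 2L) {
    stop("need completed specimens at >= 2 distinct temperatures", call. = FALSE)
  }

  y <- 1 / done$days
  temp <- done$temperature
  fit <- stats::lm(y ~ temp)
  sm <- summary(fit)
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])
  se_a <- sm$coefficients[1L, 2L]
  se_b <- sm$coefficients[2L, 2L]
  s2 <- sm$sigma^2
  n <- length(y)
  ybar <- mean(y)

  t_hat <- -a / b
  k_hat <- 1 / b
  se_t <- abs(ybar / b) * sqrt(s2 / (n * ybar^2) + (se_b / b)^2)
  se_k <- se_b / b^2
  status <- if (b <= 0) "nonphysical_slope" else "ok"
  if (status != "ok") {
    warning("fitted slope is not positive; threshold and thermal constant ",
            "are not interpretable", call. = FALSE)
  }

  structure(list(
    stage = if ("stage" %in% names(done)) as.character(done$stage[1L]) else NA_character_,
    diet = if ("diet" %in% names(done)) as.character(done$diet[1L]) else NA_character_,
    a = a, b = b, se_a = se_a, se_b = se_b, s2 = s2, n = n, ybar = ybar,
    t = t_hat, se_t = se_t, k = k_hat, se_k = abs(se_k),
    excluded_temperatures = sort(dropped), status = status
  ), class = "stage_thermal_fit")
}

#' @export
print.stage_thermal_fit <- function(x, ...) {
  cat(sprintf("Development-rate regression (%s, %s): n = %d\n",
              x$stage, x$diet, x$n))
  cat(sprintf("  y = %.6f + %.6f * T\n", x$a, x$b))
  cat(sprintf("  LDT t = %.2f +/- %.2f degC; thermal constant k = %.1f +/- %.1f DD\n",
              x$t, x$se_t, x$k, x$se_k))
  if (x$status != "ok") cat("  status:", x$status, "\n")
  invisible(x)
}

#' Pooled lower developmental threshold
#'
#' Unweighted mean of the per-stage (or per stage-by-diet cell) threshold
#' estimates, with the standard error of that mean. Pooling across stages
#' yields one practicable threshold to use for all degree-day accumulation.
#'
#' @param estimates A list of `"stage_thermal_fit"` objects, or a numeric
#'   vector of threshold estimates.
#' @return List with `t` (pooled threshold, degrees C), `se_t` (SE of the
#'   mean; `NA` for a single estimate), and `n_estimates`.
#' @examples
#' pooled_ldt(c(8.0, 11.6)) # t = 9.8
#' @export
pooled_ldt <- function(estimates) {
  if (is.list(estimates)) {
    estimates <- vapply(estimates, function(e) {
      if (!inherits(e, "stage_thermal_fit")) stop("expected stage_thermal_fit objects", call. = FALSE)
      e$t
    }, numeric(1L))
  }
  if (length(estimates) == 0L) stop("no threshold estimates supplied", call. = FALSE)
  list(t = mean(estimates),
       se_t = if (length(estimates) > 1L) stats::sd(estimates) / sqrt(length(estimates)) else NA_real_,
       n_estimates = length(estimates))
}

#' Thermal constant at a fixed lower threshold
#'
#' Degree-day requirement of a life stage computed at a fixed, externally
#' chosen threshold: each completed specimen contributes
#' `days * (temperature - ldt)` degree days, and the requirement is the mean
#' across specimens (all rearing temperatures pooled) with its standard error.
#' This standardises requirements across stages and diets once a common
#' threshold has been adopted.
#'
#' @param observations Data frame as in [fit_stage_rate()]; all rows must be
#'   completed specimens reared above `ldt`.
#' @param ldt Fixed lower developmental threshold (degrees C).
#' @return List with `stage`, `diet`, `ldt`, `k_dd` (mean degree days),
#'   `se_k_dd`, and `n`.
#' @examples
#' obs <- data.frame(temperature = 22, days = 30.5, completed = TRUE)
#' thermal_constant_fixed_ldt(obs, ldt = 9.8)$k_dd # 372.1
#' @export
thermal_constant_fixed_ldt <- function(observations, ldt) {
  check_dev_obs(observations)
  done <- observations[observations$completed, , drop = FALSE]
  if (nrow(done) == 0L) stop("no completed observations", call. = FALSE)
  if (any(done$temperature <= ldt)) {
    stop("rearing temperature at or below the fixed threshold (", ldt,
         " degC): degree-day accumulation undefined", call. = FALSE)
  }
  dd <- done$days * (done$temperature - ldt)
  list(stage = if ("stage" %in% names(done)) as.character(done$stage[1L]) else NA_character_,
       diet = if ("diet" %in% names(done)) as.character(done$diet[1L]) else NA_character_,
       ldt = ldt,
       k_dd = mean(dd),
       se_k_dd = if (length(dd) > 1L) stats::sd(dd) / sqrt(length(dd)) else NA_real_,
       n = length(dd))
}

#' Fit development-rate regressions for every stage-by-diet cell
#'
#' Convenience wrapper applying [fit_stage_rate()] to each combination of
#' `stage` and `diet` present in the data, plus, optionally, per-stage fits on
#' data combined across diets.
#'
#' @param observations Data frame with columns `stage`, `diet`,
#'   `temperature`, `days`, `completed`.
#' @param combined Also fit each stage with diets pooled (labelled diet
#'   `"combined"`)? Default `TRUE`.
#' @return A list of `"stage_thermal_fit"` objects named `"<stage>.<diet>"`.
#' @export
fit_development <- function(observations, combined = TRUE) {
  stopifnot(all(c("stage", "diet") %in% names(observations)))
  cells <- split(observations,
                 list(observations$stage, observations$diet), drop = TRUE)
  fits <- lapply(cells, fit_stage_rate)
  if (combined && length(unique(observations$diet)) > 1L) {
    pooled <- split(observations, observations$stage, drop = TRUE)
    for (st in names(pooled)) {
      d <- pooled[[st]]
      d$diet <- "combined"
      fits[[paste(st, "combined", sep = ".")]] <- fit_stage_rate(d)
    }
  }
  fits
}
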
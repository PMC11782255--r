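# Cumulative seasonal trap-catch curves on a degree-day axis and the
# three-parameter logistic flight model with variance-power heteroskedasticity.
#
# The model for the cumulative proportion of seasonal trap catch Y at
# accumulated degree days x is
#
#   Y = a / (1 + exp(-(x - b)/c)) + e,   Var(e) = sigma^2 * |v|^(2*delta)
#
# where a is the upper asymptote, b the degree-day accumulation at which Y
# reaches half its asymptote, c a growth-rate parameter (degree days), and v a
# per-observation variance covariate (by default the calendar year), so the
# residual spread may change across years. Estimation is by maximising the
# Gaussian log-likelihood, with sigma profiled out; with delta fixed at zero
# the criterion reduces exactly to ordinary nonlinear least squares.

#' Cumulative seasonal trap-catch proportions on a degree-day axis
#'
#' Converts weekly trap counts into the cumulative proportion of each
#' site-year's seasonal total, paired with the accumulated growing degree days
#' on each visit date. Site-years whose seasonal total does not exceed
#' `min_total` captures are dropped with a message; sparse seasons carry too
#' little information about the flight curve.
#'
#' @param traps Data frame with columns `site_year_id`, `year`, `visit_date`
#'   (`Date`), `count` (non-negative integers).
#' @param gdd Degree-day series from [accumulate_gdd()] covering every visit
#'   date.
#' @param min_total Seasonal-total filter: site-years are kept only when the
#'   total catch strictly exceeds this value. Default 20.
#' @return Data frame with columns `site_year_id`, `year`, `gdd`
#'   (accumulated degree days at the visit) and `prop` (cumulative proportion
#'   of the seasonal total, reaching 1 at the last visit).
#' @export
cumulative_catch <- function(traps, gdd, min_total = 20) {
  need <- c("site_year_id", "year", "visit_date", "count")
  miss <- setdiff(need, names(traps))
  if (length(miss) > 0L) {
    stop("traps is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(traps$count < 0)) stop("trap counts must be non-negative", call. = FALSE)
  traps <- traps[order(traps$site_year_id, traps$visit_date), , drop = FALSE]

  key_t <- paste(traps$site_year_id, format(traps$visit_date))
  key_g <- paste(gdd$site_year_id, format(gdd$date))
  hit <- match(key_t, key_g)
  if (anyNA(hit)) {
    bad <- utils::head(key_t[is.na(hit)], 3L)
    stop("visit date(s) not covered by the degree-day series: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }

  totals <- tapply(traps$count, traps$site_year_id, sum)
  drop_sy <- names(totals)[totals <= min_total]
  if (length(drop_sy) > 0L) {
    message("dropping ", length(drop_sy), " site-year(s) with seasonal total <= ",
            min_total, ": ", paste(drop_sy, collapse = ", "))
  }
  keep <- !(traps$site_year_id %in% drop_sy)
  if (!any(keep)) stop("no site-year exceeds the seasonal-total filter", call. = FALSE)

  out <- data.frame(
    site_year_id = traps$site_year_id[keep],
    year = traps$year[keep],
    gdd = gdd$cumulative_gdd[hit[keep]],
    prop = NA_real_
  )
  cs <- stats::ave(traps$count[keep], traps$site_year_id[keep], FUN = cumsum)
  tot <- stats::ave(traps$count[keep], traps$site_year_id[keep], FUN = sum)
  out$prop <- cs / tot
  rownames(out) <- NULL
  out
}

logistic_mean <- function(x, a, b, c) a / (1 + exp(-(x - b) / c))

resolve_var_covariate <- function(data, var_covariate) {
  if (is.numeric(var_covariate)) {
    if (length(var_covariate) != nrow(data)) {
      stop("numeric var_covariate must have one value per observation", call. = FALSE)
    }
    return(var_covariate)
  }
  switch(match.arg(var_covariate, c("year", "index")),
         year = as.numeric(data$year),
         index = as.numeric(data$year) - min(as.numeric(data$year)) + 1)
}

# Profiled negative log-likelihood in theta = (log a, b, log c[, delta]).
flight_nll_factory <- function(x, y, logv, fix_delta) {
  n <- length(x)
  function(theta) {
    a <- exp(theta[1L]); b <- theta[2L]; cc <- exp(theta[3L])
    delta <- if (is.null(fix_delta)) theta[4L] else fix_delta
    mu <- logistic_mean(x, a, b, cc)
    r <- y - mu
    s2 <- mean(r^2 * exp(-2 * delta * logv))
    if (!is.finite(s2)) return(1e10)
    s2 <- max(s2, 1e-20)
    val <- n / 2 * (log(2 * pi) + 1 + log(s2)) + delta * sum(logv)
    if (!is.finite(val)) 1e10 else val
  }
}

# Full (non-profiled) NLL on the natural scale, for the covariance hessian.
flight_nll_natural <- function(par, x, y, logv, fix_delta) {
  a <- par[1L]; b <- par[2L]; cc <- par[3L]; sigma <- par[4L]
  delta <- if (is.null(fix_delta)) par[5L] else fix_delta
  if (cc <= 0 || sigma <= 0) return(1e10)
  r <- y - logistic_mean(x, a, b, cc)
  lv <- log(sigma^2) + 2 * delta * logv
  val <- 0.5 * sum(log(2 * pi) + lv + r^2 * exp(-lv))
  if (!is.finite(val)) 1e10 else val
}

empirical_starts <- function(x, y) {
  a0 <- min(max(max(y), 0.55), 1.2)
  o <- order(x)
  xs <- x[o]; qs <- y[o] / a0
  cross <- function(p) {
    i <- which(qs >= p)[1L]
    if (is.na(i)) return(stats::quantile(xs, p, names = FALSE))
    if (i == 1L) return(xs[1L])
    x0 <- xs[i - 1L]; x1 <- xs[i]; q0 <- qs[i - 1L]; q1 <- qs[i]
    if (q1 <= q0) return(x1)
    x0 + (p - q0) / (q1 - q0) * (x1 - x0)
  }
  b0 <- cross(0.5)
  c0 <- max((cross(0.75) - cross(0.25)) / (2 * log(3)), diff(range(xs)) / 100, 1)
  list(a0 = a0, b0 = b0, c0 = c0)
}

#' Fit the logistic flight model by heteroskedastic maximum likelihood
#'
#' Fits `Y = a / (1 + exp(-(x - b)/c)) + e` with
#' `Var(e) = sigma^2 * |v|^(2*delta)` to cumulative trap-catch proportions by
#' maximising the Gaussian log-likelihood. `sigma` is profiled out and
#' `(a, b, c, delta)` are optimised with Nelder-Mead from several starting
#' points derived from the empirical 25/50/75% crossing points, followed by a
#' quasi-Newton polish. With `fix_delta = 0` the criterion is exactly the
#' ordinary nonlinear least-squares criterion.
#'
#' @param data Data frame from [cumulative_catch()] (columns `gdd`, `prop`,
#'   `year`).
#' @param fix_delta Optional fixed value for the variance-power exponent
#'   `delta`; `NULL` (default) estimates it jointly.
#' @param var_covariate Variance covariate: `"year"` (raw calendar year, the
#'   default), `"index"` (year renumbered from 1 within the data), or a
#'   numeric vector with one value per observation. Must be nonzero whenever
#'   `delta` is free.
#' @param compute_cov Compute the parameter covariance from the numerical
#'   Hessian of the full likelihood? Default `TRUE`; skipping it speeds up
#'   large model grids.
#' @param maxit Iteration cap for each optimiser run.
#' @return An object of class `"logistic_flight_fit"`: estimates `a`, `b`,
#'   `c`, `sigma`, `delta`; `vcov` (covariance of `(a, b, c)` or `NA`);
#'   `logLik`, `n`, `convergence` (0 = converged), and the model frame.
#' @export
fit_logistic_gls <- function(data, fix_delta = NULL, var_covariate = "year",
                             compute_cov = TRUE, maxit = 2000L) {
  need <- c("gdd", "prop", "year")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("data is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- data$gdd; y <- data$prop
  if (length(unique(x)) < 3L) stop("need >= 3 distinct degree-day values", call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate data: all proportions identical", call. = FALSE)
  v <- resolve_var_covariate(data, var_covariate)
  if (any(v == 0) && (is.null(fix_delta) || fix_delta != 0)) {
    stop("variance covariate contains zeros; |v|^delta undefined", call. = FALSE)
  }
  logv <- log(abs(v))
  if (!is.null(fix_delta)) stopifnot(is.numeric(fix_delta), length(fix_delta) == 1L)

  nll <- flight_nll_factory(x, y, logv, fix_delta)
  st <- empirical_starts(x, y)
  starts <- list(
    c(log(st$a0), st$b0, log(st$c0)),
    c(log(st$a0), st$b0, log(2 * st$c0)),
    c(log(min(st$a0 * 1.1, 1.3)), 0.85 * st$b0, log(st$c0)),
    c(log(st$a0), 1.15 * st$b0, log(0.6 * st$c0))
  )
  if (is.null(fix_delta)) starts <- lapply(starts, function(s) c(s, 0))

  best <- NULL
  for (s in starts) {
    run <- tryCatch({
      o1 <- stats::optim(s, nll, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-12))
      stats::optim(o1$par, nll, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12))
    }, error = function(e) NULL)
    if (is.null(run)) next
    if (is.null(best) || run$value < best$value) best <- run
  }
  if (is.null(best)) {
    stop("logistic flight fit failed: no optimiser run completed", call. = FALSE)
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("logistic flight fit failed to converge (objective not finite); ",
         "optim code ", best$convergence, call. = FALSE)
  }

  theta <- best$par
  a <- exp(theta[1L]); b <- theta[2L]; cc <- exp(theta[3L])
  delta <- if (is.null(fix_delta)) theta[4L] else fix_delta
  r <- y - logistic_mean(x, a, b, cc)
  sigma <- sqrt(max(mean(r^2 * exp(-2 * delta * logv)), 0))

  vc <- matrix(NA_real_, 3L, 3L, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  if (compute_cov && sigma > 0) {
    par_nat <- if (is.null(fix_delta)) c(a, b, cc, sigma, delta) else c(a, b, cc, sigma)
    H <- tryCatch(stats::optimHess(par_nat, flight_nll_natural,
                                   x = x, y = y, logv = logv, fix_delta = fix_delta),
                  error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(is.finite(diag(V)[1:3])) && all(diag(V)[1:3] > 0)) {
        vc[] <- V[1:3, 1:3]
      }
    }
  }

  structure(list(
    a = a, b = b, c = cc, sigma = sigma, delta = delta,
    fixed_delta = !is.null(fix_delta),
    vcov = vc,
    logLik = -best$value,
    n = length(x),
    convergence = best$convergence,
    var_covariate = if (is.numeric(var_covariate)) "numeric" else var_covariate,
    fitted = logistic_mean(x, a, b, cc),
    data = data
  ), class = "logistic_flight_fit")
}

#' @export
print.logistic_flight_fit <- function(x, ...) {
  cat("Logistic flight model (heteroskedastic ML)\n")
  cat(sprintf("  a = %.4f, b = %.2f GDD, c = %.2f GDD\n", x$a, x$b, x$c))
  cat(sprintf("  sigma = %.4f, delta = %.3f%s, n = %d, logLik = %.2f\n",
              x$sigma, x$delta, if (x$fixed_delta) " (fixed)" else "",
              x$n, x$logLik))
  invisible(x)
}

#' Predicted cumulative proportion at given degree days
#'
#' Evaluates the fitted logistic curve `a / (1 + exp(-(x - b)/c))`.
#'
#' @param fit A `"logistic_flight_fit"`.
#' @param x Accumulated growing degree days (vectorised).
#' @return Predicted cumulative proportions.
#' @export
predict_cumulative <- function(fit, x) {
  stopifnot(inherits(fit, "logistic_flight_fit"))
  logistic_mean(x, fit$a, fit$b, fit$c)
}

#' @export
predict.logistic_flight_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- if (is.data.frame(newdata)) newdata$gdd else newdata
  predict_cumulative(object, x)
}

#' Median-flight degree days with a bootstrap confidence interval
#'
#' Degree-day accumulation at which the fitted cumulative flight curve crosses
#' 0.5, in closed form `b - c * log(a/0.5 - 1)`. The interval is a parametric
#' bootstrap: parameter vectors are drawn from a multivariate normal with the
#' fitted `(a, b, c)` and their estimated covariance, the crossing is computed
#' for each draw, and the interval is taken from the quantiles of the draws
#' (draws whose curve never reaches 0.5 are discarded).
#'
#' @param fit A converged `"logistic_flight_fit"` with `a > 0.5`.
#' @param level Confidence level, default 0.95.
#' @param n_boot Number of bootstrap draws, default 2000.
#' @param seed Optional integer seed for the draws.
#' @return List with `gdd` (the point estimate), `lower`, `upper`, `level`,
#'   and `n_boot_used` (draws retained).
#' @export
median_flight_gdd <- function(fit, level = 0.95, n_boot = 2000L, seed = NULL) {
  stopifnot(inherits(fit, "logistic_flight_fit"))
  if (fit$a <= 0.5) {
    stop("fitted asymptote a = ", signif(fit$a, 4),
         " <= 0.5: the curve never reaches median flight", call. = FALSE)
  }
  est <- fit$b - fit$c * log(fit$a / 0.5 - 1)

  lower <- upper <- NA_real_
  used <- 0L
  if (all(is.finite(fit$vcov))) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(seed)
    }
    draws <- MASS::mvrnorm(n_boot, mu = c(fit$a, fit$b, fit$c), Sigma = fit$vcov)
    ok <- draws[, 1L] > 0.5 & draws[, 3L] > 0
    used <- sum(ok)
    if (used >= 100L) {
      x50 <- draws[ok, 2L] - draws[ok, 3L] * log(draws[ok, 1L] / 0.5 - 1)
      qs <- stats::quantile(x50, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
      lower <- qs[1L]; upper <- qs[2L]
    } else {
      warning("too few valid bootstrap draws for an interval", call. = FALSE)
    }
  } else {
    warning("parameter covariance unavailable; interval not computed", call. = FALSE)
  }
  list(gdd = est, lower = lower, upper = upper, level = level, n_boot_used = used)
}
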
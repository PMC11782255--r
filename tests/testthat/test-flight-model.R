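make_gdd_series <- function(id = "a", start = as.Date("2023-05-01"), n = 60,
                            dd = 10) {
  data.frame(site_year_id = id, date = start + 0:(n - 1),
             daily_dd = dd, cumulative_gdd = dd * (1:n))
}

test_that("cumulative catch converts counts to running proportions", {
  g <- make_gdd_series()
  tr <- data.frame(site_year_id = "a", year = 2023,
                   visit_date = as.Date("2023-05-01") + c(7, 14, 21),
                   count = c(5, 10, 5))
  # seasonal total 20 does not exceed the filter; relax it for the arithmetic
  cc <- cumulative_catch(tr, g, min_total = 0)
  expect_equal(cc$prop, c(0.25, 0.75, 1.0))
  expect_equal(cc$gdd, c(80, 150, 220))

  single <- data.frame(site_year_id = "a", year = 2023,
                       visit_date = as.Date("2023-05-08"), count = 30)
  expect_equal(cumulative_catch(single, g)$prop, 1.0)
})

test_that("site-years must strictly exceed the seasonal-total filter", {
  g <- rbind(make_gdd_series("a"), make_gdd_series("b"))
  tr <- data.frame(site_year_id = rep(c("a", "b"), each = 2), year = 2023,
                   visit_date = rep(as.Date("2023-05-01") + c(7, 14), 2),
                   count = c(10, 10, 10, 11)) # totals 20 and 21
  expect_message(cc <- cumulative_catch(tr, g), "dropping 1 site-year")
  expect_setequal(unique(cc$site_year_id), "b")
  expect_error(suppressMessages(
    cumulative_catch(tr[tr$site_year_id == "a", ], g)), "no site-year exceeds")
})

test_that("visits outside weather coverage and bad counts are rejected", {
  g <- make_gdd_series()
  tr <- data.frame(site_year_id = "a", year = 2023,
                   visit_date = as.Date("2023-09-01"), count = 30)
  expect_error(cumulative_catch(tr, g), "not covered")
  tr2 <- data.frame(site_year_id = "a", year = 2023,
                    visit_date = as.Date("2023-05-08"), count = -1)
  expect_error(cumulative_catch(tr2, g), "non-negative")
})

test_that("noiseless logistic data are recovered to optimiser tolerance", {
  dat <- make_logistic_data(a = 1, b = 270, c = 30, sigma = 0, seed = 1)
  fit <- fit_logistic_gls(dat, fix_delta = 0)
  expect_equal(fit$a, 1, tolerance = 1e-4)
  expect_equal(fit$b, 270, tolerance = 1e-3)
  expect_equal(fit$c, 30, tolerance = 1e-3)
  expect_equal(fit$convergence, 0)
})

test_that("the fit with delta fixed at zero matches an ordinary NLS oracle", {
  dat <- make_logistic_data(a = 0.97, b = 250, c = 35, sigma = 0.04, seed = 9)
  fit <- fit_logistic_gls(dat, fix_delta = 0)
  oracle <- nls(prop ~ a / (1 + exp(-(gdd - b) / c)), data = dat,
                start = list(a = 1, b = 260, c = 30),
                control = nls.control(maxiter = 200, tol = 1e-9, minFactor = 1e-10))
  co <- coef(oracle)
  expect_equal(fit$a, unname(co["a"]), tolerance = 1e-4)
  expect_equal(fit$b, unname(co["b"]), tolerance = 1e-4)
  expect_equal(fit$c, unname(co["c"]), tolerance = 1e-4)
})

test_that("the variance-power model detects heteroskedasticity across years", {
  set.seed(31)
  # noise scale grows with the year index
  dat <- make_logistic_data(a = 1, b = 270, c = 30, sigma = 0, n_series = 30,
                            n_visits = 18, years = 2018:2023, seed = 31)
  v <- dat$year - min(dat$year) + 1
  dat$prop <- dat$prop + rnorm(nrow(dat), 0, 0.03 * sqrt(v))
  fit <- fit_logistic_gls(dat, var_covariate = "index")
  expect_gt(fit$delta, 0.2)
  expect_lt(fit$delta, 0.8)
  expect_equal(fit$b, 270, tolerance = 0.05)
})

test_that("the heteroskedastic fit matches a generalized least squares oracle", {
  set.seed(31)
  dat <- make_logistic_data(a = 1, b = 270, c = 30, sigma = 0, n_series = 30,
                            n_visits = 18, years = 2018:2023, seed = 31)
  v <- dat$year - min(dat$year) + 1
  dat$prop <- dat$prop + rnorm(nrow(dat), 0, 0.03 * sqrt(v))
  dat$v <- v
  ours <- fit_logistic_gls(dat, var_covariate = "index")
  oracle <- nlme::gnls(prop ~ a / (1 + exp(-(gdd - b) / c)), data = dat,
                       start = c(a = 1, b = 260, c = 25),
                       weights = nlme::varPower(form = ~v))
  expect_equal(ours$a, unname(coef(oracle)["a"]), tolerance = 1e-4)
  expect_equal(ours$b, unname(coef(oracle)["b"]), tolerance = 1e-4)
  expect_equal(ours$c, unname(coef(oracle)["c"]), tolerance = 1e-4)
  expect_equal(ours$delta, as.numeric(oracle$modelStruct$varStruct), tolerance = 1e-3)
  # gnls reports sigma with a denominator degrees-of-freedom correction
  n <- nrow(dat)
  expect_equal(ours$sigma * sqrt(n / (n - 3)), oracle$sigma, tolerance = 1e-3)
})

test_that("prediction follows the logistic identities", {
  dat <- make_logistic_data(sigma = 0, seed = 2)
  fit <- fit_logistic_gls(dat, fix_delta = 0)
  expect_equal(predict_cumulative(fit, fit$b), fit$a / 2, tolerance = 1e-12)
  expect_equal(predict_cumulative(fit, 1e6), fit$a, tolerance = 1e-9)
  expect_equal(predict_cumulative(fit, -1e6), 0, tolerance = 1e-12)
  x <- seq(0, 700, by = 10)
  expect_true(all(diff(predict_cumulative(fit, x)) > 0))
})

test_that("median flight is the closed-form 0.5 crossing", {
  fit <- structure(list(a = 1, b = 270, c = 30,
                        vcov = matrix(NA_real_, 3, 3)),
                   class = "logistic_flight_fit")
  expect_warning(m <- median_flight_gdd(fit), "covariance unavailable")
  expect_equal(m$gdd, 270)

  fit$a <- 0.98
  expect_warning(m2 <- median_flight_gdd(fit), "covariance unavailable")
  expect_equal(m2$gdd, 271.2247, tolerance = 1e-4)
  # cross-check against bisection on the fitted curve
  root <- uniroot(function(x) predict_cumulative(fit, x) - 0.5,
                  c(0, 2000), tol = 1e-10)$root
  expect_equal(m2$gdd, root, tolerance = 1e-8)

  fit$a <- 0.4
  expect_error(median_flight_gdd(fit), "never reaches")
})

test_that("the bootstrap interval brackets the estimate and respects the seed", {
  dat <- make_logistic_data(a = 1, b = 270, c = 30, sigma = 0.05,
                            n_series = 12, seed = 4)
  fit <- fit_logistic_gls(dat, fix_delta = 0)
  m1 <- median_flight_gdd(fit, seed = 10)
  m2 <- median_flight_gdd(fit, seed = 10)
  expect_identical(m1, m2)
  expect_lt(m1$lower, m1$gdd)
  expect_gt(m1$upper, m1$gdd)
})

test_that("degenerate flight data produce explicit errors", {
  flat <- data.frame(site_year_id = "a", year = 2023, gdd = c(1, 2, 3),
                     prop = c(0.5, 0.5, 0.5))
  expect_error(fit_logistic_gls(flat), "degenerate")
  few <- data.frame(site_year_id = "a", year = 2023, gdd = c(1, 1),
                    prop = c(0.2, 0.9))
  expect_error(fit_logistic_gls(few), "3 distinct")
  zero_year <- make_logistic_data(sigma = 0.01, seed = 3)
  zero_year$year <- 0
  expect_error(fit_logistic_gls(zero_year), "zeros")
})
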
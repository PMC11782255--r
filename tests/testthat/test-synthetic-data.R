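test_that("generators are reproducible under a fixed seed", {
  cfg <- sim_config(seed = 5, n_site_years = 4, years = 2020:2021)
  w1 <- gen_weather(cfg); w2 <- gen_weather(cfg)
  expect_identical(w1, w2)
  t1 <- gen_trap_counts(cfg, w1); t2 <- gen_trap_counts(cfg, w1)
  expect_identical(t1, t2)
  d1 <- gen_dev_times(cfg); d2 <- gen_dev_times(cfg)
  expect_identical(d1, d2)
  # a different seed changes the draws
  w3 <- gen_weather(sim_config(seed = 6, n_site_years = 4, years = 2020:2021))
  expect_false(identical(w1$tmin, w3$tmin))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(gen_weather(sim_config(seed = 9, n_site_years = 1)))
  expect_identical(runif(1), before)
})

test_that("noiseless flat weather is exactly mean +/- half the diurnal range", {
  cfg <- sim_config(seed = 1, n_site_years = 2, years = 2022,
                    temperature = list(annual_mean = 20, amplitude = 0,
                                       daily_noise_sd = 0, year_effect_sd = 0,
                                       diurnal_range = 10))
  w <- gen_weather(cfg)
  expect_true(all(w$tmin == 15) && all(w$tmax == 25))
  expect_equal(nrow(w), 2 * 365)
})

test_that("the annual cycle amplitude appears in the monthly means", {
  cfg <- sim_config(seed = 2, n_site_years = 1, years = 2021,
                    temperature = list(amplitude = 12, daily_noise_sd = 0,
                                       year_effect_sd = 0))
  w <- gen_weather(cfg)
  monthly <- tapply((w$tmin + w$tmax) / 2, format(w$date, "%m"), mean)
  expect_equal(max(monthly) - min(monthly), 24, tolerance = 0.02 * 24)
})

test_that("weather always satisfies tmin <= tmax and has no date gaps", {
  cfg <- sim_config(seed = 3, n_site_years = 5, years = 2019:2023)
  w <- gen_weather(cfg)
  expect_true(all(w$tmin <= w$tmax))
  for (sy in unique(w$site_year_id)) {
    d <- w$date[w$site_year_id == sy]
    expect_true(all(diff(as.integer(d)) == 1))
  }
})

test_that("noise-free trap counts lie exactly on the logistic curve", {
  cfg <- sim_config(seed = 4, n_site_years = 3, years = 2021:2023,
                    temperature = list(daily_noise_sd = 0, year_effect_sd = 0),
                    flight = list(sigma = 0),
                    sampling = list(count_model = "expected"))
  w <- gen_weather(cfg)
  tr <- gen_trap_counts(cfg, w)
  g <- accumulate_gdd(w, dd_params("single_sine", ldt = 9.8, start_doy = 120))
  cc <- cumulative_catch(tr, g, min_total = 0)
  mu <- 1 / (1 + exp(-(cc$gdd - 270) / 30))
  # realised proportions renormalise by each site-year's season-end value
  expect_equal(cc$prop, mu / ave(mu, cc$site_year_id, FUN = max), tolerance = 1e-6)
})

test_that("generated trap series satisfy the cumulative-catch invariants", {
  cfg <- sim_config(seed = 8, n_site_years = 10, years = 2016:2023)
  w <- gen_weather(cfg)
  tr <- gen_trap_counts(cfg, w)
  totals <- tapply(tr$count, tr$site_year_id, sum)
  expect_true(all(totals > 20))
  g <- accumulate_gdd(w, dd_params("single_sine", ldt = 9.8, start_doy = 120))
  cc <- cumulative_catch(tr, g)
  for (sy in unique(cc$site_year_id)) {
    p <- cc$prop[cc$site_year_id == sy]
    expect_true(all(diff(p) >= 0))
    expect_equal(p[length(p)], 1)
  }
})

test_that("development times follow the linear rate model", {
  cfg <- sim_config(seed = 10, development = list(rate_noise_sd = 0, n_per_temp = 2))
  dev <- gen_dev_times(cfg)
  at22 <- dev[dev$temperature == 22 & dev$completed, ]
  expect_equal(unique(round(at22$days, 6)), round(650 / 12.2, 6))
  # designated failure temperature (above the threshold) never completes
  expect_true(all(!dev$completed[dev$temperature == 12]))
  # temperatures at or below the threshold never complete
  cfg2 <- sim_config(seed = 10, development = list(temperatures = c(9, 9.8, 17, 22)))
  dev2 <- gen_dev_times(cfg2)
  expect_true(all(!dev2$completed[dev2$temperature <= 9.8]))
  expect_true(all(dev2$completed[dev2$temperature == 17]))
})

test_that("development-rate fits recover the generating parameters", {
  cfg <- sim_config(seed = 12)
  dev <- gen_dev_times(cfg)
  fit <- suppressMessages(fit_stage_rate(dev[dev$diet == "artificial", ]))
  expect_lt(abs(fit$t - 9.8), 2 * fit$se_t + 0.5)
  expect_lt(abs(fit$k - 650), 2 * fit$se_k + 25)
})

test_that("the full count pipeline recovers the flight curve's midpoint", {
  # end-to-end: weather -> degree days -> counts -> cumulative catch -> fit.
  # Count realisation (clamping, monotonisation, Poisson rounding) perturbs
  # the ideal Gaussian model, so only the location is asserted here.
  cfg <- sim_config(seed = 2024, n_site_years = 100, years = 2014:2023)
  w <- gen_weather(cfg)
  tr <- gen_trap_counts(cfg, w)
  g <- accumulate_gdd(w, dd_params("single_sine", ldt = 9.8, start_doy = 120))
  cc <- suppressMessages(cumulative_catch(tr, g))
  fit <- fit_logistic_gls(cc, var_covariate = "index", compute_cov = FALSE)
  expect_lt(abs(fit$b - 270), 5)
  expect_gt(fit$delta, 0) # generated heteroskedasticity is picked up
})

test_that("configuration rejects unknown settings", {
  expect_error(sim_config(flight = list(banana = 1)), "unknown setting")
  expect_error(sim_config(temperature = list(daily_noise_sd = -1)))
})
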
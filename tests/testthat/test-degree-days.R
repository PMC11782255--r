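test_that("daily degree-day methods reproduce known values", {
  # threshold below tmin: all methods reduce to mean minus threshold
  expect_equal(daily_dd_simple_average(15, 25, 9.8), 10.2)
  expect_equal(daily_dd_single_triangle(15, 25, 9.8), 10.2)
  expect_equal(daily_dd_single_sine(15, 25, 9.8), 10.2)
  # threshold above tmax: zero
  expect_equal(daily_dd_simple_average(2, 8, 9.8), 0)
  expect_equal(daily_dd_single_triangle(2, 8, 9.8), 0)
  expect_equal(daily_dd_single_sine(2, 8, 9.8), 0)
  # threshold inside the diurnal range: method-specific truncation
  expect_equal(daily_dd_simple_average(5, 25, 9.8), 5.2)
  expect_equal(daily_dd_single_triangle(5, 25, 9.8), 15.2^2 / 40)
  # frozen from trapezoid integration of the sinusoid (2e5 steps)
  expect_equal(daily_dd_single_sine(5, 25, 9.8), 6.22404958, tolerance = 1e-7)
})

test_that("each method equals numerical integration of its diurnal curve", {
  triples <- random_dd_triples(300, seed = 42)
  for (m in c("simple_average", "single_triangle", "single_sine")) {
    got <- mapply(function(lo, hi, th) daily_dd(lo, hi, th, method = m),
                  triples$tmin, triples$tmax, triples$ldt)
    want <- mapply(trapezoid_dd, triples$tmin, triples$tmax, triples$ldt,
                   MoreArgs = list(method = m))
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("an upper threshold acts as a horizontal cutoff", {
  triples <- random_dd_triples(80, seed = 7)
  triples$udt <- triples$ldt + runif(80, 0.5, 15)
  for (m in c("simple_average", "single_triangle", "single_sine")) {
    got <- mapply(function(lo, hi, th, u) daily_dd(lo, hi, th, method = m, udt = u),
                  triples$tmin, triples$tmax, triples$ldt, triples$udt)
    want <- mapply(trapezoid_dd, triples$tmin, triples$tmax, triples$ldt,
                   triples$udt, MoreArgs = list(method = m))
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("daily degree days are non-increasing in the threshold and never negative", {
  set.seed(1)
  for (i in 1:50) {
    tmin <- runif(1, -5, 20); tmax <- tmin + runif(1, 0, 20)
    ldts <- sort(runif(5, tmin - 3, tmax + 3))
    for (m in c("simple_average", "single_triangle", "single_sine")) {
      vals <- vapply(ldts, function(l) daily_dd(tmin, tmax, l, method = m), numeric(1))
      expect_true(all(diff(vals) <= 1e-12))
      expect_true(all(vals >= 0))
    }
  }
})

test_that("invalid temperature order is rejected", {
  expect_error(daily_dd_simple_average(25, 15, 9.8), "tmin > tmax")
  expect_error(daily_dd_single_sine(c(1, 25), c(10, 15), 9.8), "tmin > tmax")
})

test_that("accumulation sums daily values from the start day onward", {
  w <- data.frame(site_year_id = "a", date = as.Date("2023-01-01") + 0:9,
                  tmin = 15, tmax = 25)
  g <- accumulate_gdd(w, dd_params("simple_average", ldt = 9.8, start_doy = 1))
  expect_equal(g$cumulative_gdd[10], 102)
  expect_equal(g$daily_dd, rep(10.2, 10))

  # start day after the series: nothing accumulates
  g2 <- accumulate_gdd(w, dd_params("simple_average", ldt = 9.8, start_doy = 200))
  expect_true(all(g2$daily_dd == 0) && all(g2$cumulative_gdd == 0))

  # mixed random series matches the per-day oracle
  set.seed(3)
  w3 <- data.frame(site_year_id = rep(c("a", "b"), each = 30),
                   date = rep(as.Date("2023-04-20") + 0:29, 2),
                   tmin = runif(60, 0, 15))
  w3$tmax <- w3$tmin + runif(60, 0, 15)
  g3 <- accumulate_gdd(w3, dd_params("single_sine", ldt = 9.8, start_doy = 120))
  doy <- as.integer(format(w3$date, "%j"))
  want <- mapply(trapezoid_dd, w3$tmin, w3$tmax, 9.8,
                 MoreArgs = list(method = "single_sine", n_steps = 2e4))
  want[doy < 120] <- 0
  expect_equal(g3$daily_dd, unname(want), tolerance = 1e-5)
  expect_equal(g3$cumulative_gdd, ave(g3$daily_dd, g3$site_year_id, FUN = cumsum))
  expect_true(all(ave(g3$cumulative_gdd, g3$site_year_id, FUN = function(x) min(diff(x))) >= 0))
})

test_that("accumulation rejects gaps, duplicates and empty input gracefully", {
  w <- data.frame(site_year_id = "a", date = as.Date("2023-05-01") + c(0:3, 5),
                  tmin = 10, tmax = 20)
  expect_error(accumulate_gdd(w, dd_params("single_sine", ldt = 9.8, start_doy = 1)),
               "gap in daily weather")
  wd <- data.frame(site_year_id = "a", date = as.Date("2023-05-01") + c(0, 1, 1),
                   tmin = 10, tmax = 20)
  expect_error(accumulate_gdd(wd, dd_params("single_sine", ldt = 9.8, start_doy = 1)),
               "duplicate")
  g <- accumulate_gdd(data.frame(site_year_id = character(), date = as.Date(character()),
                                 tmin = numeric(), tmax = numeric()),
                      dd_params("single_sine", ldt = 9.8, start_doy = 1))
  expect_equal(nrow(g), 0)
})

test_that("degree-day parameter validation enforces threshold order and DOY range", {
  expect_error(dd_params("single_sine", ldt = 12, udt = 10), "ldt must be below udt")
  expect_error(dd_params("single_sine", ldt = 9.8, start_doy = 0), "start_doy")
  expect_error(dd_params("single_sine", ldt = 9.8, start_doy = 400), "start_doy")
})
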
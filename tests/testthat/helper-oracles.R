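# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: degree days by brute-force numerical integration
# of the assumed diurnal curve, standard errors by nonparametric bootstrap,
# and the logistic fit by stats::nls.

# diurnal temperature curve over one day, tau in [0, 1]
diurnal_curve <- function(tau, tmin, tmax, method) {
  tm <- (tmin + tmax) / 2
  switch(method,
         simple_average = rep(tm, length(tau)),
         single_triangle = tmin + (tmax - tmin) * (1 - abs(2 * tau - 1)),
         single_sine = tm + (tmax - tmin) / 2 * sin(2 * pi * tau))
}

# trapezoid integration of the curve truncated at ldt (and capped at udt)
trapezoid_dd <- function(tmin, tmax, ldt, method, udt = NULL, n_steps = 1e5) {
  tau <- seq(0, 1, length.out = n_steps + 1)
  temp <- diurnal_curve(tau, tmin, tmax, method)
  if (!is.null(udt)) temp <- pmin(temp, udt)
  y <- pmax(temp - ldt, 0)
  sum((y[-1] + y[-length(y)]) / 2) / n_steps
}

# random (tmin, tmax, ldt) triples with ldt frequently inside [tmin, tmax]
random_dd_triples <- function(n, seed) {
  set.seed(seed)
  tmin <- runif(n, -10, 25)
  tmax <- tmin + runif(n, 0.5, 25)
  ldt <- runif(n, tmin - 5, tmax + 5)
  data.frame(tmin = tmin, tmax = tmax, ldt = ldt)
}

# noiseless / noisy linear-rate rearing data: rate = (T - t)/k + noise
make_dev_data <- function(t = 9.8, k = 650, temps = c(17, 22, 27, 32),
                          n_per = 20, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  temp <- rep(temps, each = n_per)
  rate <- (temp - t) / k + rnorm(length(temp), 0, noise_sd)
  while (any(rate <= 0)) {
    idx <- rate <= 0
    rate[idx] <- (temp[idx] - t) / k + rnorm(sum(idx), 0, noise_sd)
  }
  data.frame(temperature = temp, days = 1 / rate, completed = TRUE)
}

# bootstrap SEs of t = -a/b and k = 1/b by resampling observations; slope and
# intercept computed from first principles rather than lm()
boot_se_campbell <- function(temp, y, n_boot = 10000, seed = 1) {
  set.seed(seed)
  n <- length(y)
  t_hat <- k_hat <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    j <- sample.int(n, n, replace = TRUE)
    tt <- temp[j]; yy <- y[j]
    b <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
    a <- mean(yy) - b * mean(tt)
    t_hat[i] <- -a / b
    k_hat[i] <- 1 / b
  }
  list(se_t = sd(t_hat), se_k = sd(k_hat))
}

# cumulative-catch style data straight from the logistic, bypassing the
# weather/trap generators
make_logistic_data <- function(a = 1, b = 270, c = 30, sigma = 0,
                               n_series = 6, n_visits = 15, years = 2018:2023,
                               seed = NULL, xmax = 700) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (i in seq_len(n_series)) {
    x <- sort(runif(n_visits, 0, xmax))
    mu <- a / (1 + exp(-(x - b) / c))
    y <- mu + rnorm(n_visits, 0, sigma)
    out[[i]] <- data.frame(site_year_id = sprintf("s%02d", i),
                           year = years[(i - 1) %% length(years) + 1],
                           gdd = x, prop = y)
  }
  do.call(rbind, out)
}
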
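# Seeded synthetic weather, trap-count and rearing-data generators.
#
# The generators emulate the statistical structure the analysis assumes:
# sinusoidal annual temperature cycles with daily noise and site-year level
# offsets; weekly trap counts whose seasonal cumulative proportion follows a
# three-parameter logistic in accumulated degree days with year-level
# variance-power noise and seasonal totals comfortably above the >20-capture
# filter; and linear development rates above a lower threshold with specimen
# noise and complete failure below it (plus designated failure temperatures,
# mimicking complete mortality at a rearing temperature that is above the
# threshold but unsuitable).

# Evaluate code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generators
#'
#' Central container of generator settings with defaults chosen to resemble a
#' temperate maritime study region (a Willamette Valley-like climate), a
#' migrant flight curve centred near 270 accumulated degree days, and rearing
#' experiments at five constant temperatures on two diets. All generators are
#' reproducible: each derives its RNG stream from `seed`.
#'
#' @param seed Integer master seed.
#' @param n_site_years Number of monitored site-years.
#' @param years Calendar years over which site-years are spread (round-robin).
#' @param temperature List: `annual_mean` and `amplitude` of the sinusoidal
#'   annual cycle of daily mean temperature (degrees C, peak in mid July),
#'   `diurnal_range` (tmax - tmin), `daily_noise_sd` (day-to-day weather
#'   noise), `year_effect_sd` (site-year offsets of the annual mean,
#'   representing interannual and siting variability).
#' @param flight List: logistic parameters `a`, `b`, `c` (degree days),
#'   residual scale `sigma`, variance-power exponent `delta`, and
#'   `var_covariate` (`"index"` or `"year"`) on which the noise scale
#'   `sigma * |v|^delta` is based.
#' @param gdd List: degree-day `method`, `ldt`, and `start_doy` used to place
#'   the flight curve on the degree-day axis.
#' @param sampling List: `season_start_doy`, weekly visits for `n_weeks`,
#'   `expected_total` seasonal catch, and `count_model` (`"poisson"` draws
#'   integer counts; `"expected"` returns the exact expected counts, useful
#'   for noiseless checks).
#' @param development List: true threshold `t`, named vector `k` of thermal
#'   constants per stage, `rate_noise_sd` (specimen noise on the development
#'   rate, 1/day), `n_per_temp` specimens per temperature-by-diet cell,
#'   `temperatures`, `diets`, and `failure_temps` at which no specimen
#'   completes despite being above the threshold.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_site_years = 40L,
                       years = 2014:2023,
                       temperature = list(),
                       flight = list(),
                       gdd = list(),
                       sampling = list(),
                       development = list()) {
  merge_defaults <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad) > 0L) stop("unknown setting(s): ", paste(bad, collapse = ", "), call. = FALSE)
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_site_years = as.integer(n_site_years),
    years = as.integer(years),
    temperature = merge_defaults(list(annual_mean = 11.5, amplitude = 8,
                                      diurnal_range = 10, daily_noise_sd = 2,
                                      year_effect_sd = 1), temperature),
    flight = merge_defaults(list(a = 1, b = 270, c = 30, sigma = 0.05,
                                 delta = 0.5, var_covariate = "index"), flight),
    gdd = merge_defaults(list(method = "single_sine", ldt = 9.8,
                              start_doy = 120L), gdd),
    sampling = merge_defaults(list(season_start_doy = 121L, n_weeks = 22L,
                                   expected_total = 200,
                                   count_model = "poisson"), sampling),
    development = merge_defaults(list(t = 9.8,
                                      k = c(egg_to_adult = 650),
                                      rate_noise_sd = 0.002,
                                      n_per_temp = 20L,
                                      temperatures = c(12, 17, 22, 27, 32),
                                      diets = c("artificial", "perennial_ryegrass"),
                                      failure_temps = 12), development)
  )
  stopifnot(cfg$temperature$daily_noise_sd >= 0,
            cfg$temperature$year_effect_sd >= 0,
            cfg$flight$sigma >= 0, cfg$flight$c > 0,
            cfg$development$rate_noise_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

sim_site_year_table <- function(config) {
  yr <- rep(config$years, length.out = config$n_site_years)
  data.frame(site_year_id = sprintf("sy%03d_%d", seq_len(config$n_site_years), yr),
             year = yr)
}

#' Generate synthetic daily weather
#'
#' One full calendar year of daily minimum/maximum temperatures per site-year.
#' The daily mean follows a sinusoid peaking in mid July (day of year 196)
#' plus a site-year offset and daily Gaussian noise; tmin and tmax sit half
#' the diurnal range below and above the mean, so tmin <= tmax always holds.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `site_year_id`, `year`, `date`, `tmin`,
#'   `tmax` suitable for [accumulate_gdd()].
#' @export
gen_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$temperature
  sy <- sim_site_year_table(config)
  with_local_seed(config$seed, {
    year_eff <- stats::rnorm(nrow(sy), 0, tp$year_effect_sd)
    out <- vector("list", nrow(sy))
    for (i in seq_len(nrow(sy))) {
      d0 <- as.Date(sprintf("%d-01-01", sy$year[i]))
      d1 <- as.Date(sprintf("%d-12-31", sy$year[i]))
      dates <- seq(d0, d1, by = "day")
      doy <- as.integer(format(dates, "%j"))
      mid <- tp$annual_mean + year_eff[i] +
        tp$amplitude * cos(2 * pi * (doy - 196) / 365) +
        stats::rnorm(length(dates), 0, tp$daily_noise_sd)
      out[[i]] <- data.frame(site_year_id = sy$site_year_id[i],
                             year = sy$year[i],
                             date = dates,
                             tmin = mid - tp$diurnal_range / 2,
                             tmax = mid + tp$diurnal_range / 2)
    }
    do.call(rbind, out)
  })
}

#' Generate synthetic weekly trap counts
#'
#' Weekly visit counts per site-year whose seasonal cumulative proportion
#' follows the configured logistic curve in accumulated degree days, with
#' per-visit Gaussian noise scaled as `sigma * |v|^delta` (v the variance
#' covariate of the site-year's year), made monotone and clamped to \[0, 1\].
#' Weekly increments of the noisy cumulative curve are scaled by the expected
#' seasonal total and realised as Poisson counts (or returned as exact
#' expected counts when `count_model = "expected"`). Site-years are redrawn in
#' the rare event the seasonal total fails the >20-capture filter.
#'
#' @param config A [sim_config()].
#' @param weather Weather table from [gen_weather()] under the same config.
#' @return Data frame with columns `site_year_id`, `year`, `visit_date`,
#'   `count`.
#' @export
gen_trap_counts <- function(config, weather) {
  stopifnot(inherits(config, "sim_config"))
  fl <- config$flight
  sp <- config$sampling
  params <- dd_params(config$gdd$method, ldt = config$gdd$ldt,
                      start_doy = config$gdd$start_doy)
  gdd <- accumulate_gdd(weather, params)
  sy <- unique(weather[c("site_year_id", "year")])
  v <- switch(fl$var_covariate,
              index = as.numeric(sy$year) - min(as.numeric(sy$year)) + 1,
              year = abs(as.numeric(sy$year)),
              stop("unknown var_covariate in config", call. = FALSE))

  with_local_seed(config$seed + 1000L, {
    out <- vector("list", nrow(sy))
    for (i in seq_len(nrow(sy))) {
      g <- gdd[gdd$site_year_id == sy$site_year_id[i], , drop = FALSE]
      season0 <- g$date[1L] + (sp$season_start_doy -
                                 as.integer(format(g$date[1L], "%j")))
      visits <- season0 + 7 * (0:(sp$n_weeks - 1L))
      x <- g$cumulative_gdd[match(visits, g$date)]
      if (anyNA(x)) stop("sampling season extends beyond the weather year", call. = FALSE)
      mu <- logistic_mean(x, fl$a, fl$b, fl$c)
      sd_i <- fl$sigma * v[i]^fl$delta
      for (try in 1:20) {
        ystar <- mu + stats::rnorm(length(mu), 0, sd_i)
        ystar <- cummax(pmin(pmax(ystar, 0), 1))
        inc <- diff(c(0, ystar))
        counts <- switch(sp$count_model,
                         poisson = stats::rpois(length(inc), inc * sp$expected_total),
                         expected = inc * sp$expected_total,
                         stop("unknown count_model", call. = FALSE))
        if (sum(counts) > 20) break
      }
      if (sum(counts) <= 20) {
        stop("could not realise a seasonal total above the capture filter; ",
             "raise expected_total", call. = FALSE)
      }
      out[[i]] <- data.frame(site_year_id = sy$site_year_id[i],
                             year = sy$year[i],
                             visit_date = visits,
                             count = counts)
    }
    do.call(rbind, out)
  })
}

#' Generate synthetic constant-temperature rearing records
#'
#' Per-specimen development durations at constant rearing temperatures. Above
#' the true threshold, the development rate is `(T - t)/k` plus Gaussian
#' specimen noise (negative draws are redrawn), and days = 1/rate. At
#' temperatures at or below the threshold, and at designated failure
#' temperatures, specimens are recorded as not having completed the stage.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `specimen_id`, `temperature`, `diet`,
#'   `stage`, `days`, `completed`.
#' @export
gen_dev_times <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dv <- config$development
  grid <- expand.grid(temperature = dv$temperatures, diet = dv$diets,
                      stage = names(dv$k), rep = seq_len(dv$n_per_temp),
                      stringsAsFactors = FALSE)
  with_local_seed(config$seed + 2000L, {
    fails <- grid$temperature <= dv$t | grid$temperature %in% dv$failure_temps
    rate <- rep(NA_real_, nrow(grid))
    for (i in which(!fails)) {
      mu <- (grid$temperature[i] - dv$t) / dv$k[[grid$stage[i]]]
      r <- mu + stats::rnorm(1L, 0, dv$rate_noise_sd)
      while (r <= 0) r <- mu + stats::rnorm(1L, 0, dv$rate_noise_sd)
      rate[i] <- r
    }
    data.frame(specimen_id = sprintf("sp%05d", seq_len(nrow(grid))),
               temperature = grid$temperature,
               diet = grid$diet,
               stage = grid$stage,
               days = ifelse(fails, NA_real_, 1 / rate),
               completed = !fails)
  })
}
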
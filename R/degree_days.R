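# Daily and accumulated growing degree days from daily min/max temperatures.
#
# All three methods are horizontal-cutoff formulations: the diurnal temperature
# curve is truncated at the lower threshold (and, when supplied, capped at the
# upper threshold) and the area above the lower threshold over one day is the
# daily degree-day value. The methods differ only in the assumed diurnal curve:
# a constant at the daily mean (simple average), a symmetric triangle from tmin
# to tmax (single triangle), or a sinusoid (single sine, the Baskerville-Emin
# convention).

dd_methods <- c("simple_average", "single_triangle", "single_sine")

check_tmin_tmax <- function(tmin, tmax) {
  if (length(tmin) != length(tmax)) {
    stop("tmin and tmax must have equal length", call. = FALSE)
  }
  bad <- which(is.finite(tmin) & is.finite(tmax) & tmin > tmax)
  if (length(bad) > 0L) {
    stop("tmin > tmax at position(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Area above `thr` of the assumed diurnal curve, per method, no upper cap.
# With an upper threshold u >= thr, the horizontal-cutoff value is
# area(thr) - area(u), because max(min(T, u) - thr, 0) = max(T - thr, 0) - max(T - u, 0).
dd_area_above <- function(tmin, tmax, thr, method) {
  tm <- (tmin + tmax) / 2
  switch(method,
    simple_average = pmax(tm - thr, 0),
    single_triangle = {
      out <- pmax(tm - thr, 0)
      part <- thr > tmin & thr < tmax
      out[part] <- (tmax[part] - thr)^2 / (2 * (tmax[part] - tmin[part]))
      out
    },
    single_sine = {
      out <- pmax(tm - thr, 0)
      part <- thr > tmin & thr < tmax
      if (any(part)) {
        a <- (tmax[part] - tmin[part]) / 2
        theta <- asin((thr - tm[part]) / a)
        out[part] <- ((tm[part] - thr) * (pi / 2 - theta) + a * cos(theta)) / pi
      }
      out
    },
    stop("unknown degree-day method: ", method, call. = FALSE)
  )
}

dd_one_method <- function(tmin, tmax, ldt, udt, method) {
  check_tmin_tmax(tmin, tmax)
  if (!is.null(udt)) {
    if (!is.numeric(udt) || length(udt) != 1L || udt <= ldt) {
      stop("udt must be a single number greater than ldt", call. = FALSE)
    }
    dd_area_above(tmin, tmax, ldt, method) - dd_area_above(tmin, tmax, udt, method)
  } else {
    dd_area_above(tmin, tmax, ldt, method)
  }
}

#' Daily degree days, simple average method
#'
#' Degree days for one day computed as `max((tmin + tmax)/2 - ldt, 0)`:
#' the daily mean temperature is truncated at the lower developmental
#' threshold after averaging. With an upper threshold `udt`, the mean is
#' additionally capped at `udt` before subtracting `ldt`.
#'
#' @param tmin,tmax Daily minimum and maximum temperature (degrees C).
#'   Vectorised; `tmin <= tmax` is required elementwise.
#' @param ldt Lower developmental threshold (degrees C).
#' @param udt Optional upper developmental threshold (degrees C), applied as a
#'   horizontal cutoff. Default `NULL` (no upper threshold).
#' @return Numeric vector of daily degree days (never negative).
#' @examples
#' daily_dd_simple_average(15, 25, 9.8) # 10.2
#' daily_dd_simple_average(2, 8, 9.8)   # 0
#' @export
daily_dd_simple_average <- function(tmin, tmax, ldt, udt = NULL) {
  dd_one_method(tmin, tmax, ldt, udt, "simple_average")
}

#' Daily degree days, single triangle method
#'
#' The diurnal temperature course is modelled as a symmetric triangle rising
#' from `tmin` to `tmax` and back; the daily degree-day value is the area of
#' that triangle above the lower threshold, normalised to one day. When the
#' threshold lies strictly between `tmin` and `tmax` this equals
#' `(tmax - ldt)^2 / (2 * (tmax - tmin))`.
#'
#' @inheritParams daily_dd_simple_average
#' @return Numeric vector of daily degree days.
#' @examples
#' daily_dd_single_triangle(5, 25, 9.8) # 5.776
#' @export
daily_dd_single_triangle <- function(tmin, tmax, ldt, udt = NULL) {
  dd_one_method(tmin, tmax, ldt, udt, "single_triangle")
}

#' Daily degree days, single sine method
#'
#' The diurnal temperature course is modelled as a sinusoid with mean
#' `(tmin + tmax)/2` and amplitude `(tmax - tmin)/2`; the daily degree-day
#' value is the area of the sinusoid above the lower threshold. For a
#' threshold strictly between `tmin` and `tmax`, with `Tm` the mean,
#' `alpha` the amplitude and `theta = asin((ldt - Tm)/alpha)`, this is
#' `((Tm - ldt) * (pi/2 - theta) + alpha * cos(theta)) / pi`.
#'
#' @inheritParams daily_dd_simple_average
#' @return Numeric vector of daily degree days.
#' @examples
#' daily_dd_single_sine(5, 25, 9.8) # about 6.224
#' @export
daily_dd_single_sine <- function(tmin, tmax, ldt, udt = NULL) {
  dd_one_method(tmin, tmax, ldt, udt, "single_sine")
}

#' Daily degree days by method name
#'
#' Dispatches to one of [daily_dd_simple_average()],
#' [daily_dd_single_triangle()] or [daily_dd_single_sine()].
#'
#' @inheritParams daily_dd_simple_average
#' @param method One of `"simple_average"`, `"single_triangle"`,
#'   `"single_sine"`.
#' @return Numeric vector of daily degree days.
#' @export
daily_dd <- function(tmin, tmax, ldt, method = dd_methods, udt = NULL) {
  method <- match.arg(method, dd_methods)
  dd_one_method(tmin, tmax, ldt, udt, method)
}

#' Degree-day accumulation parameters
#'
#' Bundles the settings of a degree-day accumulation: calculation method,
#' lower (and optional upper) developmental threshold, and the day of year on
#' which accumulation begins (the fixed-date biofix).
#'
#' @param method Degree-day calculation method.
#' @param ldt Lower developmental threshold (degrees C).
#' @param udt Optional upper developmental threshold (degrees C); default
#'   absent.
#' @param start_doy Day of year (1 January = 1) at which accumulation starts,
#'   inclusive; in 1..366.
#' @return An object of class `"dd_params"`.
#' @examples
#' dd_params("single_sine", ldt = 9.8, start_doy = 120)
#' @export
dd_params <- function(method = dd_methods, ldt, udt = NULL, start_doy = 1L) {
  method <- match.arg(method, dd_methods)
  stopifnot(is.numeric(ldt), length(ldt) == 1L, is.finite(ldt))
  if (!is.null(udt) && udt <= ldt) stop("ldt must be below udt", call. = FALSE)
  start_doy <- as.integer(start_doy)
  if (is.na(start_doy) || start_doy < 1L || start_doy > 366L) {
    stop("start_doy must be in 1..366", call. = FALSE)
  }
  structure(list(method = method, ldt = ldt, udt = udt, start_doy = start_doy),
            class = "dd_params")
}

#' @export
print.dd_params <- function(x, ...) {
  cat(sprintf("Degree-day parameters: %s, LDT %.2f degC%s, start DOY %d\n",
              x$method, x$ldt,
              if (is.null(x$udt)) "" else sprintf(", UDT %.2f degC", x$udt),
              x$start_doy))
  invisible(x)
}

check_weather <- function(weather) {
  need <- c("site_year_id", "date", "tmin", "tmax")
  miss <- setdiff(need, names(weather))
  if (length(miss) > 0L) {
    stop("weather is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(weather$date, "Date")) {
    stop("weather$date must be of class Date", call. = FALSE)
  }
  check_tmin_tmax(weather$tmin, weather$tmax)
  dup <- duplicated(weather[c("site_year_id", "date")])
  if (any(dup)) {
    stop("duplicate dates within a site-year: ",
         paste(utils::head(paste(weather$site_year_id[dup], weather$date[dup]), 3L),
               collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Accumulate growing degree days over daily weather
#'
#' Computes daily degree days for every date on or after the accumulation
#' start day-of-year and their running sum (accumulated GDD), independently
#' per site-year. Days before the start day contribute zero. Missing calendar
#' days between the start day and the end of a site-year's record are an
#' error: silent gaps would bias the accumulation.
#'
#' @param weather Data frame with columns `site_year_id`, `date` (`Date`),
#'   `tmin`, `tmax` (degrees C), one row per site-year per day.
#' @param params A [dd_params()] object.
#' @return A data frame with columns `site_year_id`, `date`, `daily_dd`,
#'   `cumulative_gdd`, sorted by site-year and date.
#' @examples
#' w <- data.frame(site_year_id = "a",
#'                 date = as.Date("2023-01-01") + 0:9,
#'                 tmin = 15, tmax = 25)
#' accumulate_gdd(w, dd_params("simple_average", ldt = 9.8, start_doy = 1))
#' @export
accumulate_gdd <- function(weather, params) {
  stopifnot(inherits(params, "dd_params"))
  if (nrow(weather) == 0L) {
    return(data.frame(site_year_id = character(), date = as.Date(character()),
                      daily_dd = numeric(), cumulative_gdd = numeric()))
  }
  check_weather(weather)
  weather <- weather[order(weather$site_year_id, weather$date), , drop = FALSE]
  doy <- as.integer(format(weather$date, "%j"))
  active <- doy >= params$start_doy

  # gap check: within each site-year, dates in the accumulation window must be
  # consecutive calendar days
  by_sy <- split(seq_len(nrow(weather)), weather$site_year_id, drop = TRUE)
  for (idx in by_sy) {
    d <- weather$date[idx][active[idx]]
    if (length(d) > 1L && any(diff(as.integer(d)) != 1L)) {
      gap_at <- d[which(diff(as.integer(d)) != 1L)[1L]]
      stop("gap in daily weather for site-year '",
           weather$site_year_id[idx[1L]], "' after ", format(gap_at),
           call. = FALSE)
    }
  }

  dd <- numeric(nrow(weather))
  dd[active] <- dd_one_method(weather$tmin[active], weather$tmax[active],
                              params$ldt, params$udt, params$method)
  out <- data.frame(site_year_id = weather$site_year_id,
                    date = weather$date,
                    daily_dd = dd)
  out$cumulative_gdd <- stats::ave(out$daily_dd, out$site_year_id, FUN = cumsum)
  rownames(out) <- NULL
  out
}
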
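# Projection of life-stage calendar windows forward from a biofix date using
# fixed-threshold degree-day requirements.

# Degree-day requirements per life stage at LDT 9.8 degC, by rearing diet.
# "combined" pools both diets and splits the larval stage into small
# (instars 1-3) and large (instars 4-6) larvae; the single-diet sets carry the
# whole larval stage. egg_to_adult is the independently estimated requirement
# for one full generation (not the sum of the stage increments, which differs
# slightly because each stage is estimated on its own specimens).
stage_threshold_presets <- list(
  combined = list(
    stages = c(egg_hatch = 75.72, small_larva_end = 142.16,
               large_larva_end = 230.28, pupa_end = 186.67),
    egg_to_adult = 648.47
  ),
  ryegrass = list(
    stages = c(egg_hatch = 75.72, larva_end = 315.92, pupa_end = 178.64),
    egg_to_adult = 601.98
  ),
  artificial = list(
    stages = c(egg_hatch = 75.72, larva_end = 384.08, pupa_end = 193.22),
    egg_to_adult = 658.71
  )
)

#' Life-stage degree-day checkpoints
#'
#' Degree-day requirements of successive black cutworm life stages at a common
#' lower developmental threshold of 9.8 degrees C, expressed as per-stage
#' increments from the biofix (adult arrival/oviposition). Three presets are
#' available: `"combined"` (both rearing diets pooled; the general model, with
#' the larval stage split into small and large larvae), `"ryegrass"` (the
#' grass seed crop-specific model), and `"artificial"`. Increments can be
#' overridden for custom models.
#'
#' @param preset One of `"combined"`, `"ryegrass"`, `"artificial"`.
#' @param ldt Lower developmental threshold the requirements refer to.
#' @param stages Optional named numeric vector of per-stage degree-day
#'   increments (in developmental order) replacing the preset's.
#' @param egg_to_adult Optional full-generation degree-day requirement.
#' @return Object of class `"stage_thresholds"`: `ldt`, `stages` (increments),
#'   `checkpoints` (cumulative degree days from biofix), `egg_to_adult`,
#'   `preset`.
#' @examples
#' stage_thresholds("combined")
#' @export
stage_thresholds <- function(preset = c("combined", "ryegrass", "artificial"),
                             ldt = 9.8, stages = NULL, egg_to_adult = NULL) {
  preset <- match.arg(preset)
  p <- stage_threshold_presets[[preset]]
  if (!is.null(stages)) {
    if (is.null(names(stages)) || any(!nzchar(names(stages)))) {
      stop("stages must be a named numeric vector", call. = FALSE)
    }
    p$stages <- stages
  }
  if (!is.null(egg_to_adult)) p$egg_to_adult <- egg_to_adult
  if (any(p$stages < 0)) stop("stage increments must be non-negative", call. = FALSE)
  structure(list(ldt = ldt, stages = p$stages, checkpoints = cumsum(p$stages),
                 egg_to_adult = p$egg_to_adult, preset = preset),
            class = "stage_thresholds")
}

#' @export
print.stage_thresholds <- function(x, ...) {
  cat(sprintf("Stage degree-day checkpoints (preset '%s', LDT %.1f degC):\n",
              x$preset, x$ldt))
  for (nm in names(x$checkpoints)) {
    cat(sprintf("  %-16s +%7.2f DD (cumulative %7.2f)\n",
                nm, x$stages[[nm]], x$checkpoints[[nm]]))
  }
  cat(sprintf("  %-16s %16.2f DD (one generation)\n", "egg_to_adult", x$egg_to_adult))
  invisible(x)
}

#' Project life-stage windows forward from a biofix date
#'
#' Accumulates growing degree days from the biofix date (inclusive) and
#' reports, for each stage checkpoint, the first date whose cumulative
#' accumulation reaches the checkpoint. With a constant daily accumulation of
#' `d` degree days, a checkpoint `q` is reached on day `ceiling(q/d)` counting
#' the biofix date as day 1. If the weather record ends before a checkpoint is
#' reached, the remaining stages are returned with `NA` dates and the result
#' is flagged truncated.
#'
#' @param biofix_date `Date`; the event (for flight-based models, the
#'   predicted median flight date) from which accumulation starts.
#' @param weather Daily weather for one site-year (see [accumulate_gdd()]),
#'   covering the biofix date onward.
#' @param thresholds A [stage_thresholds()] object.
#' @param method Degree-day calculation method, default `"single_sine"`.
#' @param udt Optional upper threshold.
#' @return Object of class `"stage_forecast"`: data frame `stages` with
#'   columns `stage`, `checkpoint_gdd`, `date`, `days_after_biofix` (biofix
#'   date = day 1), plus `biofix_date`, `truncated`, `adult_emergence` (the
#'   full-generation checkpoint projected the same way).
#' @export
project_stage_windows <- function(biofix_date, weather, thresholds,
                                  method = dd_methods, udt = NULL) {
  stopifnot(inherits(thresholds, "stage_thresholds"))
  method <- match.arg(method, dd_methods)
  biofix_date <- as.Date(biofix_date)
  w <- weather[weather$date >= biofix_date, , drop = FALSE]
  if (nrow(w) == 0L || w$date[1L] != biofix_date) {
    stop("weather does not cover the biofix date ", format(biofix_date), call. = FALSE)
  }
  if (length(unique(w$site_year_id)) > 1L) {
    stop("forecast weather must be a single site-year", call. = FALSE)
  }
  w <- w[order(w$date), , drop = FALSE]
  if (any(diff(as.integer(w$date)) != 1L)) {
    stop("gap in daily weather after the biofix date", call. = FALSE)
  }
  dd <- dd_one_method(w$tmin, w$tmax, thresholds$ldt, udt, method)
  cum <- cumsum(dd)

  first_reach <- function(q) {
    if (q <= 0) return(1L)
    i <- which(cum >= q)[1L]
    if (is.na(i)) NA_integer_ else i
  }
  idx <- vapply(thresholds$checkpoints, first_reach, integer(1L))
  stages <- data.frame(
    stage = names(thresholds$checkpoints),
    checkpoint_gdd = unname(thresholds$checkpoints),
    date = w$date[idx],
    days_after_biofix = idx
  )
  adult_idx <- first_reach(thresholds$egg_to_adult)
  truncated <- anyNA(idx) || is.na(adult_idx)
  if (truncated) {
    warning("weather record ends before every checkpoint is reached; ",
            "forecast truncated", call. = FALSE)
  }
  structure(list(stages = stages,
                 biofix_date = biofix_date,
                 adult_emergence = list(checkpoint_gdd = thresholds$egg_to_adult,
                                        date = w$date[adult_idx],
                                        days_after_biofix = adult_idx),
                 preset = thresholds$preset,
                 method = method,
                 truncated = truncated),
            class = "stage_forecast")
}

#' @export
print.stage_forecast <- function(x, ...) {
  cat(sprintf("Stage forecast from biofix %s (preset '%s', %s)%s\n",
              format(x$biofix_date), x$preset, x$method,
              if (x$truncated) " [TRUNCATED]" else ""))
  print(x$stages, row.names = FALSE)
  cat(sprintf("  adult emergence (one generation, %.2f DD): %s\n",
              x$adult_emergence$checkpoint_gdd,
              if (is.na(x$adult_emergence$days_after_biofix)) "beyond record"
              else format(x$adult_emergence$date)))
  invisible(x)
}
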
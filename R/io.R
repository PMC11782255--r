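# CSV readers and writers for the package's external interfaces. Readers
# validate the schema and report offending rows by their line number in the
# file (header = line 1).

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

# data row i sits on file line i + 1 (after the header)
lines_of <- function(rows) paste(rows + 1L, collapse = ", ")

parse_iso_date <- function(x, what, path) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad) > 0L) {
    stop("unparseable ", what, " (expected YYYY-MM-DD) in ", path,
         " at line(s): ", lines_of(utils::head(bad, 5L)), call. = FALSE)
  }
  d
}

#' Read a daily weather CSV
#'
#' Expects columns `site_year_id`, `date` (ISO 8601), `tmin_c`, `tmax_c`, one
#' row per site-year per day. Rows with `tmin_c > tmax_c` or duplicate dates
#' within a site-year are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `site_year_id`, `date` (`Date`), `tmin`,
#'   `tmax`, ready for [accumulate_gdd()].
#' @export
read_weather_csv <- function(path) {
  df <- read_csv_checked(path, c("site_year_id", "date", "tmin_c", "tmax_c"))
  date <- parse_iso_date(df$date, "date", path)
  bad <- which(df$tmin_c > df$tmax_c)
  if (length(bad) > 0L) {
    stop("tmin_c > tmax_c in ", path, " at line(s): ",
         lines_of(utils::head(bad, 5L)), call. = FALSE)
  }
  dup <- which(duplicated(paste(df$site_year_id, date)))
  if (length(dup) > 0L) {
    stop("duplicate site-year/date in ", path, " at line(s): ",
         lines_of(utils::head(dup, 5L)), call. = FALSE)
  }
  out <- data.frame(site_year_id = as.character(df$site_year_id),
                    date = date, tmin = df$tmin_c, tmax = df$tmax_c)
  if ("year" %in% names(df)) out$year <- df$year
  out
}

#' Write a daily weather CSV
#'
#' Inverse of [read_weather_csv()].
#'
#' @param weather Data frame with `site_year_id`, `date`, `tmin`, `tmax`.
#' @param path Output path.
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(data.frame(site_year_id = weather$site_year_id,
                              date = format(weather$date, "%Y-%m-%d"),
                              tmin_c = weather$tmin,
                              tmax_c = weather$tmax),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trap-count CSV
#'
#' Expects columns `site_year_id`, `year`, `visit_date` (ISO 8601), `count`.
#' Negative counts are an error; visits out of date order within a site-year
#' are sorted with a warning.
#'
#' @param path Path to the CSV file.
#' @return Data frame ready for [cumulative_catch()].
#' @export
read_trap_csv <- function(path) {
  df <- read_csv_checked(path, c("site_year_id", "year", "visit_date", "count"))
  visit_date <- parse_iso_date(df$visit_date, "visit_date", path)
  bad <- which(df$count < 0)
  if (length(bad) > 0L) {
    stop("negative count in ", path, " at line(s): ",
         lines_of(utils::head(bad, 5L)), call. = FALSE)
  }
  out <- data.frame(site_year_id = as.character(df$site_year_id),
                    year = as.integer(df$year),
                    visit_date = visit_date,
                    count = df$count)
  o <- order(out$site_year_id, out$visit_date)
  if (any(o != seq_along(o))) {
    warning("visit dates out of order in ", path, "; sorted", call. = FALSE)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write a trap-count CSV
#'
#' Inverse of [read_trap_csv()].
#'
#' @param traps Data frame with `site_year_id`, `year`, `visit_date`, `count`.
#' @param path Output path.
#' @export
write_trap_csv <- function(traps, path) {
  utils::write.csv(data.frame(site_year_id = traps$site_year_id,
                              year = traps$year,
                              visit_date = format(traps$visit_date, "%Y-%m-%d"),
                              count = traps$count),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a constant-temperature rearing CSV
#'
#' Expects columns `specimen_id`, `temperature_c`, `diet`, `stage`, `days`,
#' `completed` (logical or 0/1). Completed records must have `days > 0`.
#'
#' @param path Path to the CSV file.
#' @return Data frame ready for [fit_stage_rate()] / [fit_development()].
#' @export
read_development_csv <- function(path) {
  df <- read_csv_checked(path, c("specimen_id", "temperature_c", "diet",
                                 "stage", "days", "completed"))
  completed <- as.logical(df$completed)
  bad <- which(is.na(completed))
  if (length(bad) > 0L) {
    stop("unparseable completed flag in ", path, " at line(s): ",
         lines_of(utils::head(bad, 5L)), call. = FALSE)
  }
  bad <- which(completed & (is.na(df$days) | df$days <= 0))
  if (length(bad) > 0L) {
    stop("completed rows must have days > 0 in ", path, " at line(s): ",
         lines_of(utils::head(bad, 5L)), call. = FALSE)
  }
  data.frame(specimen_id = as.character(df$specimen_id),
             temperature = df$temperature_c,
             diet = as.character(df$diet),
             stage = as.character(df$stage),
             days = df$days,
             completed = completed)
}

#' Write a rearing-record CSV
#'
#' Inverse of [read_development_csv()].
#'
#' @param dev Data frame with `specimen_id`, `temperature`, `diet`, `stage`,
#'   `days`, `completed`.
#' @param path Output path.
#' @export
write_development_csv <- function(dev, path) {
  utils::write.csv(data.frame(specimen_id = dev$specimen_id,
                              temperature_c = dev$temperature,
                              diet = dev$diet,
                              stage = dev$stage,
                              days = dev$days,
                              completed = dev$completed),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# round for serialization: 6 significant digits on all floating-point output
round_sig <- function(x, digits = 6) {
  if (is.numeric(x)) return(signif(x, digits))
  if (is.data.frame(x) || is.list(x)) return(lapply_keep(x, round_sig, digits = digits))
  x
}

lapply_keep <- function(x, f, ...) {
  out <- lapply(x, f, ...)
  attributes(out) <- attributes(x)
  out
}

#' Write a result object as JSON
#'
#' Serialises a (possibly nested) list of results with all floating-point
#' values at 6 significant digits, so repeated runs with the same inputs and
#' seed produce byte-identical files.
#'
#' @param x List to serialise.
#' @param path Output path.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(round_sig(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", Date = "ISO8601")
  invisible(path)
}
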
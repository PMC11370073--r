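# Readers and writers for the package's plain-text formats.
#
# Raw recording CSV layout (compatible with common raw-actigraphy CSV
# exports): three metadata lines, then a column header and one row per
# sample:
#   serial,<subject id>
#   start_time,<ISO-8601 local datetime>
#   sample_rate,<Hz>
#   x,y,z
#   -0.012,0.004,0.998
#   ...

#' Write a raw recording to CSV
#'
#' @param recording A [raw_recording].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  header <- c(
    paste0("serial,", recording$subject_id),
    paste0("start_time,", format(recording$start_time, "%Y-%m-%dT%H:%M:%S")),
    paste0("sample_rate,", format(recording$sample_rate))
  )
  writeLines(header, path)
  readr::write_csv(recording$data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a raw recording from CSV
#'
#' Parses the documented raw CSV layout; malformed metadata or non-numeric
#' sample rows are reported with their line numbers.
#'
#' @param path Input file path.
#'
#' @return A [raw_recording].
#' @export
read_raw_recording <- function(path) {
  meta <- readLines(path, n = 4)
  if (length(meta) < 4) abort_arg("file too short: missing header lines.")
  get_field <- function(line, key, lineno) {
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2 || parts[1] != key) {
      abort_arg(sprintf("line %d: expected '%s,<value>', got '%s'", lineno, key, line))
    }
    paste(parts[-1], collapse = ",")
  }
  serial <- get_field(meta[1], "serial", 1)
  start_raw <- get_field(meta[2], "start_time", 2)
  start_time <- as.POSIXct(start_raw, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (is.na(start_time)) abort_arg("line 2: unparseable start_time (want ISO-8601).")
  rate <- suppressWarnings(as.numeric(get_field(meta[3], "sample_rate", 3)))
  if (is.na(rate) || rate <= 0) abort_arg("line 3: sample_rate must be a positive number.")
  if (!identical(trimws(meta[4]), "x,y,z")) {
    abort_arg("line 4: expected column header 'x,y,z'.")
  }
  # non-numeric rows surface as NA and are reported with line numbers below
  body <- suppressWarnings(readr::read_csv(path,
    skip = 3, col_types = readr::cols(
      x = readr::col_double(), y = readr::col_double(), z = readr::col_double()
    ),
    progress = FALSE
  ))
  bad <- which(!stats::complete.cases(body))
  if (length(bad) > 0) {
    abort_arg(sprintf(
      "non-numeric sample values at line(s) %s",
      paste(head(bad + 4L, 5), collapse = ", ")
    ))
  }
  raw_recording(body, serial, start_time, rate)
}

COHORT_REQUIRED <- c(
  "child_id", "wave", "sex", "age_years",
  "maternal_work", "dwelling", "yard", "season", "covid"
)

#' Read a cohort covariate table
#'
#' Reads and validates a cohort table: required columns present, sex limited
#' to male/female, unique child-wave keys. Rows with missing covariate
#' values are dropped with a message (complete-case analysis), mirroring an
#' analysis sample restricted to children with all covariates.
#'
#' @param path CSV path with at least the columns `child_id`, `wave`,
#'   `sex`, `age_years`, `maternal_work`, `dwelling`, `yard`, `season`,
#'   `covid`.
#'
#' @return Typed tibble.
#' @export
read_cohort_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(COHORT_REQUIRED, names(d))
  if (length(missing) > 0) {
    abort_arg(paste0("missing required columns: ", paste(missing, collapse = ", ")))
  }
  bad_sex <- setdiff(unique(d$sex[!is.na(d$sex)]), c("male", "female"))
  if (length(bad_sex) > 0) {
    abort_arg(paste0("sex must be male/female; found: ", paste(bad_sex, collapse = ", ")))
  }
  if (anyDuplicated(d[c("child_id", "wave")]) > 0) {
    abort_arg("duplicate child-wave rows; keys must be unique.")
  }
  incomplete <- !stats::complete.cases(d[COHORT_REQUIRED])
  if (any(incomplete)) {
    message(sprintf("dropping %d row(s) with missing covariates", sum(incomplete)))
    d <- d[!incomplete, , drop = FALSE]
  }
  d |>
    dplyr::mutate(
      sex = factor(.data$sex, levels = c("female", "male")),
      maternal_work = factor(.data$maternal_work),
      dwelling = factor(.data$dwelling),
      yard = factor(.data$yard),
      season = factor(.data$season),
      covid = as.logical(.data$covid)
    )
}
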
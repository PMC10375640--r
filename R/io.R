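#' @name validators
#' @title Table validators
#' @description
#' Each validator checks one input table: required columns are fatal
#' (the error names the missing column); malformed rows — non-positive or
#' comparator-coded creatinine values (`"<5"`), unparseable timestamps,
#' unknown sex codes, stop before start — are dropped and reported in a
#' row-level issue tibble; exact duplicate rows are deduplicated with a
#' warning. Timestamps are parsed as ISO-8601 and normalized to UTC, so
#' zone offsets in the input are folded into a single clock.
#' @param x A data frame as read from the corresponding delimited file.
#' @return A list with `data` (the cleaned tibble) and `issues`
#'   (tibble with `row`, `issue`).
NULL

require_columns <- function(x, cols, table) {
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "%s table is missing required column(s): %s",
      table, paste(missing_cols, collapse = ", ")
    ))
  }
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(.as_utc(x))
  }
  suppressWarnings(readr::parse_datetime(as.character(x)))
}

parse_num <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  # comparator-coded values ("<5", ">1000") become NA and are rejected,
  # never coerced
  suppressWarnings(as.numeric(ifelse(grepl("^[0-9eE.+-]+$", trimws(x)),
    trimws(x), NA
  )))
}

dedupe <- function(x, table, issues) {
  dup <- duplicated(x)
  if (any(dup)) {
    warn(sprintf(
      "%s table: %d exact duplicate row(s) removed", table, sum(dup)
    ))
    issues <- bind_rows(issues, tibble(
      row = which(dup), issue = "duplicate row (removed)"
    ))
    x <- x[!dup, , drop = FALSE]
  }
  list(data = x, issues = issues)
}

#' @rdname validators
#' @export
validate_measurements <- function(x) {
  require_columns(
    x,
    c("patient_id", "timestamp", "creatinine_umol_l", "department", "specialty"),
    "measurements"
  )
  x <- as_tibble(x)
  issues <- tibble(row = integer(), issue = character())
  d <- dedupe(x, "measurements", issues)
  x <- d$data
  issues <- d$issues

  ts <- parse_timestamp(x$timestamp)
  val <- parse_num(x$creatinine_umol_l)
  bad_ts <- is.na(ts)
  bad_val <- !bad_ts & (is.na(val) | !is.finite(val) | val <= 0)
  if (any(bad_ts)) {
    issues <- bind_rows(issues, tibble(
      row = which(bad_ts), issue = "unparseable timestamp"
    ))
  }
  if (any(bad_val)) {
    issues <- bind_rows(issues, tibble(
      row = which(bad_val),
      issue = "non-positive or non-numeric creatinine"
    ))
  }
  keep <- !bad_ts & !bad_val
  out <- x[keep, , drop = FALSE] %>%
    mutate(
      patient_id = as.character(.data$patient_id),
      timestamp = ts[keep],
      creatinine_umol_l = val[keep],
      department = as.character(.data$department),
      specialty = as.character(.data$specialty)
    )
  list(data = out, issues = issues)
}

#' @rdname validators
#' @export
validate_demographics <- function(x) {
  require_columns(
    x,
    c("patient_id", "birth_date", "sex", "icu_flag", "covid_flag", "dialysis_flag"),
    "demographics"
  )
  x <- as_tibble(x)
  issues <- tibble(row = integer(), issue = character())
  d <- dedupe(x, "demographics", issues)
  x <- d$data
  issues <- d$issues

  bd <- suppressWarnings(as.Date(as.character(x$birth_date)))
  sex_clean <- tolower(trimws(as.character(x$sex)))
  bad_bd <- is.na(bd)
  bad_sex <- !bad_bd & !sex_clean %in% c("female", "male")
  if (any(bad_bd)) {
    issues <- bind_rows(issues, tibble(
      row = which(bad_bd), issue = "unparseable birth_date"
    ))
  }
  if (any(bad_sex)) {
    issues <- bind_rows(issues, tibble(
      row = which(bad_sex), issue = "unknown sex code"
    ))
  }
  keep <- !bad_bd & !bad_sex
  out <- x[keep, , drop = FALSE] %>%
    mutate(
      patient_id = as.character(.data$patient_id),
      birth_date = bd[keep],
      sex = sex_clean[keep],
      icu_flag = as_flag(.data$icu_flag),
      covid_flag = as_flag(.data$covid_flag),
      dialysis_flag = as_flag(.data$dialysis_flag)
    )
  list(data = out, issues = issues)
}

as_flag <- function(x) {
  if (is.logical(x)) {
    return(!is.na(x) & x)
  }
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes")
}

#' @rdname validators
#' @export
validate_medications <- function(x) {
  require_columns(x, c("patient_id", "drug_id", "start", "stop"), "medications")
  x <- as_tibble(x)
  issues <- tibble(row = integer(), issue = character())
  d <- dedupe(x, "medications", issues)
  x <- d$data
  issues <- d$issues

  ts_start <- parse_timestamp(x$start)
  stop_raw <- as.character(x$stop)
  stop_missing <- is.na(x$stop) | stop_raw == ""
  ts_stop <- parse_timestamp(x$stop)
  ts_stop[stop_missing] <- NA
  bad_start <- is.na(ts_start)
  bad_stop <- !stop_missing & is.na(ts_stop)
  bad_order <- !bad_start & !bad_stop & !stop_missing & ts_stop < ts_start
  for (flag_issue in list(
    list(bad_start, "unparseable start"),
    list(bad_stop, "unparseable stop"),
    list(bad_order, "stop precedes start")
  )) {
    if (any(flag_issue[[1]])) {
      issues <- bind_rows(issues, tibble(
        row = which(flag_issue[[1]]), issue = flag_issue[[2]]
      ))
    }
  }
  keep <- !bad_start & !bad_stop & !bad_order
  out <- x[keep, , drop = FALSE] %>%
    mutate(
      patient_id = as.character(.data$patient_id),
      drug_id = as.character(.data$drug_id),
      start = ts_start[keep],
      stop = ts_stop[keep]
    )
  list(data = out, issues = issues)
}

#' Validate the three pipeline inputs together
#'
#' @param measurements,demographics,medications Data frames as read from
#'   the delimited inputs.
#' @param nephro_list Character vector of nephrotoxic drug identifiers.
#' @return A list with the cleaned tables and a combined `issues` tibble
#'   (columns `table`, `row`, `issue`).
#' @export
validate_inputs <- function(measurements, demographics, medications,
                            nephro_list = character()) {
  vm <- validate_measurements(measurements)
  vd <- validate_demographics(demographics)
  vmed <- validate_medications(medications)
  issues <- bind_rows(
    mutate(vm$issues, table = "measurements"),
    mutate(vd$issues, table = "demographics"),
    mutate(vmed$issues, table = "medications")
  )
  list(
    measurements = vm$data,
    demographics = vd$data,
    medications = vmed$data,
    nephro_list = nephro_list,
    issues = issues[, c("table", "row", "issue")]
  )
}

#' @name readers
#' @title Read the pipeline's delimited input tables
#' @description
#' Thin wrappers over [readr::read_csv()] that parse and validate one
#' table each (see the validators for the row-level rules). The
#' nephrotoxic list is a plain text file with one drug identifier per
#' line; blank lines and `#` comments are ignored.
#' @param path Path to the file.
#' @param quiet Suppress the issue-count message.
#' @return The validated tibble, with the issue tibble attached as
#'   attribute `"issues"`.
NULL

read_checked <- function(path, validator, quiet) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  v <- validator(raw)
  if (!quiet && nrow(v$issues) > 0L) {
    message(sprintf(
      "%s: %d row(s) rejected during validation", basename(path), nrow(v$issues)
    ))
  }
  attr(v$data, "issues") <- v$issues
  v$data
}

#' @rdname readers
#' @export
read_measurements <- function(path, quiet = FALSE) {
  read_checked(path, validate_measurements, quiet)
}

#' @rdname readers
#' @export
read_demographics <- function(path, quiet = FALSE) {
  read_checked(path, validate_demographics, quiet)
}

#' @rdname readers
#' @export
read_medications <- function(path, quiet = FALSE) {
  read_checked(path, validate_medications, quiet)
}

#' @rdname readers
#' @export
read_nephro_list <- function(path, quiet = FALSE) {
  x <- trimws(readr::read_lines(path))
  x <- x[x != "" & !startsWith(x, "#")]
  if (!quiet) message(sprintf("%s: %d nephrotoxic drug(s)", basename(path), length(x)))
  unique(x)
}

#' Read an alert table previously written by the pipeline
#'
#' @param path Path to an `alerts.csv` written by [run_pipeline()] or the
#'   command-line interface.
#' @return An alert tibble with parsed timestamps.
#' @export
read_alerts <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    timestamp = readr::col_datetime(),
    creatinine_umol_l = readr::col_double(),
    department = readr::col_character(),
    specialty = readr::col_character(),
    sex = readr::col_character(),
    age_years = readr::col_double(),
    outcome = readr::col_character(),
    delta_fired = readr::col_logical(),
    delta_value = readr::col_double(),
    ratio_fired = readr::col_logical(),
    ratio_value = readr::col_double(),
    baseline_status = readr::col_character(),
    baseline_value = readr::col_double(),
    baseline_time = readr::col_datetime(),
    .default = readr::col_guess()
  ))
}

#' Write a simulated cohort to delimited files
#'
#' Emits `measurements.csv`, `demographics.csv`, `medications.csv`,
#' `truth.csv` and `nephro_list.txt` into `dir`, in the formats the
#' package's own readers consume (timestamps ISO-8601 UTC).
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"))
  readr::write_csv(cohort$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(cohort$medications, file.path(dir, "medications.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  writeLines(cohort$nephro_list, file.path(dir, "nephro_list.txt"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory holding the cohort files.
#' @param quiet Suppress validation messages.
#' @return A list with `measurements`, `demographics`, `medications`,
#'   `nephro_list` and (when present) `truth`.
#' @export
read_cohort <- function(dir, quiet = TRUE) {
  out <- list(
    measurements = read_measurements(file.path(dir, "measurements.csv"), quiet),
    demographics = read_demographics(file.path(dir, "demographics.csv"), quiet),
    medications = read_medications(file.path(dir, "medications.csv"), quiet),
    nephro_list = read_nephro_list(file.path(dir, "nephro_list.txt"), quiet)
  )
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- readr::read_csv(truth_path, col_types = readr::cols(
      patient_id = readr::col_character(),
      event_time = readr::col_datetime(),
      fold_change = readr::col_double(),
      delta = readr::col_double(),
      detectable = readr::col_logical()
    ))
  }
  out
}
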
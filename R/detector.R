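#' Select the baseline creatinine for an index time
#'
#' The baseline is the minimum creatinine in the 7 days strictly before the
#' index time. When that window is empty, the most recent value between 365
#' and 7 days before the index time is used instead ("fallback" baseline).
#' When neither window holds a value there is no baseline and the flowchart
#' reports "unable to compute".
#'
#' Window conventions: the 7-day window is `(t - 7 d, t)`, open at both
#' ends, so a value exactly 7 days old falls in the fallback window
#' `[t - 365 d, t - 7 d]` (closed at both ends). Among equal-valued minima
#' the most recent timestamp is reported; the baseline value is unaffected.
#'
#' @param history Tibble of one patient's measurements strictly before
#'   `index_time`, with columns `timestamp` and `creatinine_umol_l`.
#' @param index_time POSIXct index instant.
#' @param config An [aki_config()].
#' @return A one-row tibble: `status` (`"found_7d"`, `"found_365d"` or
#'   `"none"`), `baseline_value`, `baseline_time`.
#' @export
select_baseline <- function(history, index_time, config = aki_config()) {
  check_history(history, index_time)
  res <- baseline_scan(
    as.numeric(history$timestamp), history$creatinine_umol_l,
    as.numeric(.as_utc(index_time)),
    .days(config$baseline_window_days), .days(config$fallback_window_days)
  )
  tibble(
    status = res$status,
    baseline_value = res$value,
    baseline_time = if (is.na(res$time)) as.POSIXct(NA, tz = "UTC") else
      as.POSIXct(res$time, origin = "1970-01-01", tz = "UTC")
  )
}

# numeric-time kernel shared by select_baseline() and detect_alerts();
# t must be sorted ascending (ties resolved by ingestion order)
baseline_scan <- function(t, v, it, bw, fw) {
  in7 <- t > it - bw & t < it
  if (any(in7)) {
    vmin <- min(v[in7])
    idx <- which(in7 & v == vmin)
    idx <- idx[length(idx)] # most recent of equal-valued minima
    return(list(status = "found_7d", value = vmin, time = t[idx]))
  }
  infb <- t >= it - fw & t <= it - bw
  if (any(infb)) {
    # most recent value in the fallback window; timestamp ties resolved by
    # ingestion order (t is sorted, so take the last qualifying index)
    idx <- max(which(infb & t == max(t[infb])))
    return(list(status = "found_365d", value = v[idx], time = t[idx]))
  }
  list(status = "none", value = NA_real_, time = NA_real_)
}

#' Absolute-increase criterion over 48 hours
#'
#' Fires when the index value exceeds the minimum creatinine observed in
#' the preceding 48 hours by at least the delta threshold (26.5 umol/L by
#' default). The window `(t - 48 h, t)` excludes the index measurement.
#'
#' @inheritParams select_baseline
#' @param index_value Creatinine of the index measurement, umol/L.
#' @return One-row tibble: `delta_fired`, `delta_value` (NA when the window
#'   is empty).
#' @export
evaluate_delta_48h <- function(history, index_time, index_value,
                               config = aki_config()) {
  check_history(history, index_time)
  res <- delta_scan(
    as.numeric(history$timestamp), history$creatinine_umol_l,
    as.numeric(.as_utc(index_time)), index_value,
    .hours(config$delta_window_hours), config$delta_threshold
  )
  tibble(delta_fired = res$fired, delta_value = res$delta)
}

delta_scan <- function(t, v, it, iv, w, thr) {
  in48 <- t > it - w & t < it
  if (!any(in48)) {
    return(list(fired = FALSE, delta = NA_real_))
  }
  delta <- iv - min(v[in48])
  list(fired = delta >= thr, delta = delta)
}

#' Fold-change criterion against the baseline
#'
#' Fires when the index value is at least `ratio_threshold` (1.5 by
#' default) times the baseline from [select_baseline()]. Both the 7-day
#' minimum and the 365-day fallback baseline participate.
#'
#' @param index_value Creatinine of the index measurement, umol/L.
#' @param baseline A one-row tibble from [select_baseline()] with
#'   `status != "none"`.
#' @inheritParams select_baseline
#' @return One-row tibble: `ratio_fired`, `ratio_value`.
#' @export
evaluate_ratio <- function(index_value, baseline, config = aki_config()) {
  if (!is.data.frame(baseline) || nrow(baseline) != 1L) {
    abort("`baseline` must be a one-row baseline result")
  }
  if (baseline$status == "none") {
    abort("evaluate_ratio() requires a baseline; got status = \"none\"")
  }
  ratio <- index_value / baseline$baseline_value
  tibble(ratio_fired = ratio >= config$ratio_threshold, ratio_value = ratio)
}

check_history <- function(history, index_time) {
  stopifnot(is.data.frame(history))
  if (!all(c("timestamp", "creatinine_umol_l") %in% names(history))) {
    abort("history needs columns `timestamp` and `creatinine_umol_l`")
  }
  if (nrow(history) == 0L) {
    return(invisible(TRUE))
  }
  if (any(!is.finite(history$creatinine_umol_l) |
    history$creatinine_umol_l <= 0)) {
    abort("creatinine values must be positive and finite")
  }
  if (any(.as_utc(history$timestamp) >= .as_utc(index_time))) {
    abort("history must lie strictly before `index_time`")
  }
  invisible(TRUE)
}

#' Evaluate the full AKI flowchart for one measurement
#'
#' Composes [select_baseline()], [evaluate_delta_48h()] and
#' [evaluate_ratio()] into a single alert record. The outcome is
#' `"positive"` when either criterion fires, `"unable_to_compute"` when no
#' baseline exists within 365 days (in which case the 48-hour window is
#' necessarily empty too), else `"negative"`. The alert is displayed in the
#' EHR only for adults outside the dialysis department and only for
#' non-negative outcomes.
#'
#' @inheritParams select_baseline
#' @param index One-row tibble with `patient_id`, `timestamp`,
#'   `creatinine_umol_l`, `department`, `specialty`.
#' @param demographics Tibble with `patient_id`, `birth_date` (Date) and
#'   `sex`; may omit the patient, in which case the alert is computed but
#'   never displayed and a warning is raised.
#' @return A one-row alert tibble (see [detect_alerts()] for the columns).
#' @export
evaluate_flowchart <- function(history, index, demographics,
                               config = aki_config()) {
  stopifnot(is.data.frame(index), nrow(index) == 1L)
  check_history(history, index$timestamp[[1L]])
  meas <- dplyr::bind_rows(history, index)
  meas$patient_id <- index$patient_id[[1L]]
  alerts <- detect_alerts(meas, demographics, config = config)
  alerts[nrow(alerts), , drop = FALSE]
}

#' Run the AKI rule engine over a measurement table
#'
#' Evaluates the flowchart for every measurement, using only measurements
#' of the same patient that precede it. Measurements are ordered by
#' patient, timestamp and ingestion order (row order breaks timestamp
#' ties deterministically).
#'
#' @param measurements Tibble with `patient_id`, `timestamp` (POSIXct),
#'   `creatinine_umol_l` (> 0), `department`, `specialty`.
#' @param demographics Tibble with `patient_id`, `birth_date`, `sex` and
#'   logical `icu_flag`, `covid_flag`, `dialysis_flag` (flags optional
#'   here; used downstream). Patients missing from this table trigger one
#'   warning and their alerts carry `display = FALSE`.
#' @param config An [aki_config()].
#' @return A tibble with one alert per measurement: the measurement
#'   columns plus `age_years`, `outcome`, `delta_fired`, `delta_value`,
#'   `ratio_fired`, `ratio_value`, `baseline_status`, `baseline_value`,
#'   `baseline_time`, `display`, `memo`.
#' @export
detect_alerts <- function(measurements, demographics, config = aki_config()) {
  req <- c("patient_id", "timestamp", "creatinine_umol_l", "department", "specialty")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "measurements table lacks columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(measurements) == 0L) {
    return(empty_alerts())
  }
  if (any(!is.finite(measurements$creatinine_umol_l) |
    measurements$creatinine_umol_l <= 0)) {
    abort("creatinine values must be positive and finite; validate inputs first")
  }

  m <- measurements %>%
    mutate(
      timestamp = .as_utc(.data$timestamp),
      .ingest = row_number()
    ) %>%
    arrange(.data$patient_id, .data$timestamp, .data$.ingest)

  demo <- demographics[, intersect(
    c("patient_id", "birth_date", "sex"),
    names(demographics)
  ), drop = FALSE]
  m <- left_join(m, demo, by = "patient_id")
  n_missing_demo <- sum(is.na(m$birth_date))
  if (n_missing_demo > 0L) {
    warn(sprintf(
      "%d measurement(s) belong to patients absent from demographics; their alerts are never displayed",
      n_missing_demo
    ))
  }
  m$age_years <- as.numeric(difftime(
    m$timestamp, .as_utc(as.POSIXct(m$birth_date)),
    units = "days"
  )) / 365.25

  bw <- .days(config$baseline_window_days)
  fw <- .days(config$fallback_window_days)
  dw <- .hours(config$delta_window_hours)

  n <- nrow(m)
  outcome <- character(n)
  delta_fired <- logical(n)
  delta_value <- rep(NA_real_, n)
  ratio_fired <- logical(n)
  ratio_value <- rep(NA_real_, n)
  b_status <- character(n)
  b_value <- rep(NA_real_, n)
  b_time <- rep(NA_real_, n)

  tnum <- as.numeric(m$timestamp)
  vals <- m$creatinine_umol_l
  pid <- m$patient_id
  starts <- which(!duplicated(pid))
  ends <- c(starts[-1L] - 1L, n)

  for (g in seq_along(starts)) {
    lo <- starts[g]
    hi <- ends[g]
    for (i in lo:hi) {
      ht <- if (i > lo) tnum[lo:(i - 1L)] else numeric(0)
      hv <- if (i > lo) vals[lo:(i - 1L)] else numeric(0)
      bl <- baseline_scan(ht, hv, tnum[i], bw, fw)
      dl <- delta_scan(ht, hv, tnum[i], vals[i], dw, config$delta_threshold)
      b_status[i] <- bl$status
      b_value[i] <- bl$value
      b_time[i] <- bl$time
      delta_fired[i] <- dl$fired
      delta_value[i] <- dl$delta
      if (bl$status != "none") {
        ratio_value[i] <- vals[i] / bl$value
        ratio_fired[i] <- ratio_value[i] >= config$ratio_threshold
      }
      outcome[i] <- if (bl$status == "none" && !any(ht > tnum[i] - dw)) {
        "unable_to_compute"
      } else if (delta_fired[i] || ratio_fired[i]) {
        "positive"
      } else {
        "negative"
      }
    }
  }

  alerts <- m %>%
    mutate(
      outcome = outcome,
      delta_fired = delta_fired,
      delta_value = delta_value,
      ratio_fired = ratio_fired,
      ratio_value = ratio_value,
      baseline_status = b_status,
      baseline_value = b_value,
      baseline_time = as.POSIXct(b_time, origin = "1970-01-01", tz = "UTC"),
      display = .data$outcome != "negative" &
        !is.na(.data$age_years) &
        .data$age_years >= config$adult_age_years &
        !(.data$department %in% config$dialysis_departments),
      memo = vapply(outcome, render_memo, character(1))
    ) %>%
    select(-".ingest", -"birth_date")
  alerts
}

empty_alerts <- function() {
  tibble(
    patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    creatinine_umol_l = double(), department = character(),
    specialty = character(), sex = character(), age_years = double(),
    outcome = character(), delta_fired = logical(), delta_value = double(),
    ratio_fired = logical(), ratio_value = double(),
    baseline_status = character(), baseline_value = double(),
    baseline_time = as.POSIXct(character(), tz = "UTC"),
    display = logical(), memo = character()
  )
}

#' Memo text attached to an alert
#'
#' Positive alerts carry the actionable advisory shown on hover in the
#' EHR; unable-to-compute alerts explain the missing 365-day baseline;
#' negative alerts carry no text and are never shown.
#'
#' @param outcome `"positive"`, `"unable_to_compute"` or `"negative"`.
#' @param phone_numbers Named character vector of placeholders for the
#'   pharmacy, internal medicine and nephrology contact numbers.
#' @return A single string (empty for negative outcomes).
#' @export
render_memo <- function(outcome,
                        phone_numbers = c(
                          pharmacy = "(phone number)",
                          internal_medicine = "(phone number)",
                          nephrology = "(phone number)"
                        )) {
  switch(outcome,
    positive = paste(
      "According to the KDIGO guidelines, this patient has acute kidney injury (AKI).",
      "Follow up the kidney function.",
      sprintf(
        "Be aware of the use of nephrotoxic medication and consider changing medication dosage. If necessary, please contact the pharmacist %s.",
        phone_numbers[["pharmacy"]]
      ),
      sprintf(
        "For questions about kidney function deterioration, consider consult with the internal medicine %s or nephrology department %s.",
        phone_numbers[["internal_medicine"]], phone_numbers[["nephrology"]]
      ),
      "For more info, please find the AKI-alert document in the hospital protocol system.",
      sep = "\n"
    ),
    unable_to_compute = "Not able to evaluate according to the KDIGO guidelines due to no available PCr measurement in the previous 365 days.",
    negative = "",
    abort(sprintf("unknown alert outcome %s", outcome))
  )
}
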
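#' Phone-notification decisions for an alert stream
#'
#' The laboratory phones the requesting physician for a positive alert
#' unless (a) the department is on the phone-exclusion list (dialysis,
#' ICU, COVID ward by default — those patients are already under close
#' surveillance; the alert is still displayed outside dialysis), or
#' (b) a phoned alert occurred within the suppression window (7 days) with
#' no intervening non-triggering measurement. A negative or
#' unable-to-compute measurement after the last phoned alert ends the
#' suppression, so a patient alerting on day 1 and day 3 with a
#' non-triggering measurement on day 2 is phoned on both days.
#'
#' @param alerts Alert tibble from [detect_alerts()] (all outcomes; the
#'   non-triggering measurements drive the suppression reset).
#' @param config An [aki_config()].
#' @return `alerts` with columns `phone` (logical) and
#'   `phone_suppressed_reason` (`"none"`, `"within_7d_of_phoned_alert"`,
#'   `"excluded_department"`; `NA` for non-positive rows).
#' @export
phone_decisions <- function(alerts, config = aki_config()) {
  a <- alerts %>%
    mutate(.ingest = row_number()) %>%
    arrange(.data$patient_id, .data$timestamp, .data$.ingest)
  n <- nrow(a)
  phone <- logical(n)
  reason <- rep(NA_character_, n)

  tnum <- as.numeric(a$timestamp)
  supp <- .days(config$phone_suppression_days)
  pid <- a$patient_id
  starts <- which(!duplicated(pid))
  ends <- c(starts[-1L] - 1L, n)

  for (g in seq_along(starts)) {
    last_phoned <- -Inf
    reset_since <- FALSE
    for (i in starts[g]:ends[g]) {
      if (a$outcome[i] == "positive") {
        if (a$department[i] %in% config$phone_excluded_departments) {
          reason[i] <- "excluded_department"
        } else if (is.finite(last_phoned) &&
          tnum[i] - last_phoned < supp && !reset_since) {
          reason[i] <- "within_7d_of_phoned_alert"
        } else {
          phone[i] <- TRUE
          reason[i] <- "none"
          last_phoned <- tnum[i]
          reset_since <- FALSE
        }
      } else {
        # negative and unable-to-compute measurements interrupt suppression
        reset_since <- TRUE
      }
    }
  }
  a %>%
    mutate(phone = phone, phone_suppressed_reason = reason) %>%
    arrange(.data$.ingest) %>%
    select(-".ingest")
}

#' Phone decision for a single positive alert
#'
#' Single-alert form of the policy in [phone_decisions()], given the
#' patient's prior phoned-alert times and prior non-triggering measurement
#' times.
#'
#' @param alert_time POSIXct time of the positive alert.
#' @param department Department code of the alert.
#' @param phoned_times POSIXct times of the patient's previously phoned
#'   alerts (may be empty).
#' @param nontriggering_times POSIXct times of the patient's prior
#'   negative / unable-to-compute measurements (may be empty).
#' @param config An [aki_config()].
#' @return One-row tibble: `phone`, `phone_suppressed_reason`.
#' @export
decide_phone <- function(alert_time, department, phoned_times = NULL,
                         nontriggering_times = NULL,
                         config = aki_config()) {
  t <- as.numeric(.as_utc(alert_time))
  if (department %in% config$phone_excluded_departments) {
    return(tibble(phone = FALSE, phone_suppressed_reason = "excluded_department"))
  }
  pt <- as.numeric(.as_utc(phoned_times))
  pt <- pt[pt < t]
  if (length(pt) > 0L) {
    last_phoned <- max(pt)
    nt <- as.numeric(.as_utc(nontriggering_times))
    reset <- any(nt > last_phoned & nt < t)
    if (t - last_phoned < .days(config$phone_suppression_days) && !reset) {
      return(tibble(
        phone = FALSE,
        phone_suppressed_reason = "within_7d_of_phoned_alert"
      ))
    }
  }
  tibble(phone = TRUE, phone_suppressed_reason = "none")
}

#' Assign positive alerts to AKI episodes
#'
#' Greedy anchored segmentation: a patient's first unassigned positive
#' alert starts an episode; every subsequent positive alert strictly
#' within `episode_window_days` of the episode *start* joins it; the first
#' alert at or beyond that boundary starts the next episode. The episode
#' inherits department and specialty from its first alert, which anchors
#' all endpoint windows.
#'
#' @param alerts Alert tibble; only rows with `outcome == "positive"` are
#'   segmented.
#' @param config An [aki_config()].
#' @return `alerts` with an `episode_id` column (`NA` for non-positive
#'   rows), ids of the form `<patient_id>/E<k>`.
#' @export
assign_episode_ids <- function(alerts, config = aki_config()) {
  a <- alerts %>%
    mutate(.ingest = row_number()) %>%
    arrange(.data$patient_id, .data$timestamp, .data$.ingest)
  n <- nrow(a)
  episode_id <- rep(NA_character_, n)
  tnum <- as.numeric(a$timestamp)
  w <- .days(config$episode_window_days)
  pid <- a$patient_id
  starts <- which(!duplicated(pid))
  ends <- c(starts[-1L] - 1L, n)
  for (g in seq_along(starts)) {
    anchor <- -Inf
    k <- 0L
    for (i in starts[g]:ends[g]) {
      if (a$outcome[i] != "positive") next
      if (tnum[i] - anchor >= w) {
        k <- k + 1L
        anchor <- tnum[i]
      }
      episode_id[i] <- sprintf("%s/E%d", pid[i], k)
    }
  }
  a %>%
    mutate(episode_id = episode_id) %>%
    arrange(.data$.ingest) %>%
    select(-".ingest")
}

#' Segment positive alerts into AKI episodes
#'
#' @inheritParams assign_episode_ids
#' @return A tibble with one row per episode: `episode_id`, `patient_id`,
#'   `start_time`, `start_department`, `start_specialty`, `n_alerts`.
#' @export
segment_episodes <- function(alerts, config = aki_config()) {
  a <- assign_episode_ids(alerts, config) %>%
    filter(!is.na(.data$episode_id)) %>%
    arrange(.data$patient_id, .data$timestamp)
  if (nrow(a) == 0L) {
    return(tibble(
      episode_id = character(), patient_id = character(),
      start_time = as.POSIXct(character(), tz = "UTC"),
      start_department = character(), start_specialty = character(),
      n_alerts = integer()
    ))
  }
  a %>%
    group_by(.data$episode_id, .data$patient_id) %>%
    summarise(
      start_time = .data$timestamp[1L],
      start_department = .data$department[1L],
      start_specialty = .data$specialty[1L],
      n_alerts = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$patient_id, .data$start_time)
}

#' Restrict episodes to the analysis population
#'
#' Episodes of patients in the COVID cohort and episodes starting in an
#' intensive-care department are excluded from the before-after analysis
#' (those patients receive different treatment and are already under high
#' surveillance).
#'
#' @param episodes Episode tibble from [segment_episodes()].
#' @param demographics Demographics tibble with `patient_id` and logical
#'   `covid_flag`.
#' @param covid_cohort_ids Optional extra patient ids to treat as COVID
#'   cohort.
#' @param config An [aki_config()].
#' @return A list: `episodes` (retained rows), `exclusions` (tibble with
#'   `reason`, `n`), `n_excluded`.
#' @export
filter_analysis_population <- function(episodes, demographics,
                                       covid_cohort_ids = NULL,
                                       config = aki_config()) {
  covid_ids <- unique(c(
    covid_cohort_ids,
    if ("covid_flag" %in% names(demographics)) {
      demographics$patient_id[isTRUE_vec(demographics$covid_flag)]
    }
  ))
  is_covid <- episodes$patient_id %in% covid_ids
  is_icu <- episodes$start_department %in% config$icu_departments
  keep <- !is_covid & !is_icu
  list(
    episodes = episodes[keep, , drop = FALSE],
    exclusions = tibble(
      reason = c("covid_cohort", "icu_department"),
      # a COVID-cohort episode starting in ICU is counted once, as COVID
      n = c(sum(is_covid), sum(is_icu & !is_covid))
    ),
    n_excluded = sum(!keep)
  )
}

isTRUE_vec <- function(x) !is.na(x) & x
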
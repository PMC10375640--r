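#' Configuration of the synthetic EHR cohort generator
#'
#' Defines the study conditions the simulator emulates: per-period cohort
#' size, sex-specific baseline creatinine, measurement cadence by care
#' setting, the injected AKI excursion, and the per-period endpoint
#' probabilities (2-day follow-up, nephrotoxic exposure, 7-day stop).
#' Defaults are pilot-scale: 1000 patients per six-month period with an
#' 88% injected-event rate yields roughly 850 analysable AKI episodes per
#' period, and the endpoint probabilities (0.57/0.66 follow-up,
#' 0.59/0.63 exposure, 0.78/0.85 stop) are of the magnitude seen in
#' hospital before-after awareness pilots.
#'
#' Baseline creatinine is log-normal by sex (median 70 umol/L female,
#' 85 umol/L male, sdlog 0.2) — a population-plausible stand-in, not an
#' empirical fit. Injected events multiply the latent creatinine by
#' `fold_change` at the event time, after which it decays back to baseline
#' over `recovery_days`. Measurement noise is multiplicative log-normal;
#' set `noise_sd = 0` for exact, noise-free trajectories.
#'
#' @param n_patients Named integer vector, patients per period
#'   (`before`, `after`).
#' @param seed Integer master seed. Independent sub-streams are derived
#'   per table (demographics/latent events, measurements, medications) so
#'   regenerating one table never perturbs the others.
#' @param baseline_creatinine List with `female` and `male` entries, each
#'   `c(meanlog, sdlog)` of the log-normal baseline distribution.
#' @param noise_sd Multiplicative measurement noise (sd on the log scale).
#' @param cadence_days Named vector of mean inter-measurement gaps (days)
#'   by setting: `ED`, `ward`, `outpatient`, `ICU`.
#' @param n_history Named integer vector: pre-event measurements per
#'   setting.
#' @param aki_event_rate Probability a patient receives an injected AKI
#'   event.
#' @param aki_profile List: `fold_change` (peak/baseline), `rise_hours`
#'   (time from last normal value to peak), `recovery_days` (decay back to
#'   baseline).
#' @param p_followup Named per-period probability of a creatinine
#'   measurement within 2 days of the event.
#' @param p_nephro_use Named per-period probability of active nephrotoxic
#'   exposure at the event.
#' @param p_stop Named per-period probability that an active nephrotoxic
#'   drug is stopped within 7 days (conditional on exposure).
#' @param department_mix Named weights over the analysis settings
#'   (`ED`, `ward`, `outpatient`).
#' @param p_icu Probability a patient is an ICU patient (department
#'   `"ICU"`; excluded from the analysis population).
#' @param p_covid_cohort Probability a patient carries the COVID-cohort
#'   flag (excluded from the analysis population).
#' @param p_female Probability of female sex.
#' @param age_mean,age_sd Adult age distribution (normal, truncated to
#'   18-95 years).
#' @param nephro_drugs,other_drugs Drug identifier pools; `nephro_drugs`
#'   doubles as the default nephrotoxic list.
#' @param periods Period table, see [default_periods()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = c(before = 1000L, after = 1000L),
                       seed = 1L,
                       baseline_creatinine = list(
                         female = c(meanlog = log(70), sdlog = 0.20),
                         male = c(meanlog = log(85), sdlog = 0.20)
                       ),
                       noise_sd = 0.04,
                       cadence_days = c(ED = 0.5, ward = 1, outpatient = 30, ICU = 0.5),
                       n_history = c(ED = 4L, ward = 5L, outpatient = 2L, ICU = 4L),
                       aki_event_rate = 0.88,
                       aki_profile = list(
                         fold_change = 2.0, rise_hours = 24, recovery_days = 7
                       ),
                       p_followup = c(before = 0.57, after = 0.66),
                       p_nephro_use = c(before = 0.592, after = 0.632),
                       p_stop = c(before = 0.778, after = 0.853),
                       department_mix = c(ED = 0.17, ward = 0.56, outpatient = 0.27),
                       p_icu = 0.02,
                       p_covid_cohort = 0.02,
                       p_female = 0.46,
                       age_mean = 60, age_sd = 16,
                       nephro_drugs = c(
                         "gentamicin", "vancomycin", "tacrolimus",
                         "ibuprofen", "lisinopril"
                       ),
                       other_drugs = c("paracetamol", "omeprazole", "metoprolol"),
                       periods = default_periods()) {
  probs <- c(
    aki_event_rate, p_followup, p_nephro_use, p_stop,
    p_icu, p_covid_cohort, p_female
  )
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (any(cadence_days <= 0) || any(n_patients < 0)) {
    abort("cadences must be positive and cohort sizes non-negative")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (aki_profile$fold_change <= 0 || aki_profile$recovery_days <= 0) {
    abort("aki_profile must have positive fold_change and recovery_days")
  }
  for (nm in c("before", "after")) {
    for (field in c("n_patients", "p_followup", "p_nephro_use", "p_stop")) {
      if (!nm %in% names(get(field))) {
        abort(sprintf("`%s` must be named with before/after entries", field))
      }
    }
  }
  structure(
    list(
      n_patients = n_patients, seed = as.integer(seed),
      baseline_creatinine = baseline_creatinine, noise_sd = noise_sd,
      cadence_days = cadence_days, n_history = n_history,
      aki_event_rate = aki_event_rate, aki_profile = aki_profile,
      p_followup = p_followup, p_nephro_use = p_nephro_use,
      p_stop = p_stop, department_mix = department_mix,
      p_icu = p_icu, p_covid_cohort = p_covid_cohort,
      p_female = p_female, age_mean = age_mean, age_sd = age_sd,
      nephro_drugs = nephro_drugs, other_drugs = other_drugs,
      periods = periods
    ),
    class = "sim_config"
  )
}

with_stream_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a synthetic EHR cohort
#'
#' Generates the three input tables of the pipeline — creatinine
#' measurements, medication records, demographics — plus a truth log of
#' the injected AKI events. Each patient receives a visit anchor drawn
#' uniformly inside their period, a setting-specific run of pre-anchor
#' measurements (dense for ED/ward/ICU, sparse for outpatients, whose
#' baseline therefore comes from the 365-day fallback), and, with
#' probability `aki_event_rate`, an injected creatinine excursion at the
#' anchor. The excursion modifies the latent trajectory before noise is
#' sampled, so detectability is a property of the construction: an event
#' is flagged `detectable` when its fold change reaches the ratio
#' threshold, or its absolute rise reaches the delta threshold while a
#' measurement precedes it within 48 hours.
#'
#' Follow-up measurements (within 48 h), later measurements, nephrotoxic
#' exposure and stop times are drawn per period with the configured
#' probabilities, so before-after effect sizes are known by construction.
#'
#' @param config A [sim_config()].
#' @param rule_config An [aki_config()]; supplies the thresholds used to
#'   mark injected events as detectable.
#' @return A list of class `sim_cohort`: `measurements`, `medications`,
#'   `demographics`, `truth`, `nephro_list`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), rule_config = aki_config()) {
  stopifnot(inherits(config, "sim_config"))
  patients <- with_stream_seed(
    config$seed,
    simulate_patients(config)
  )
  measurements <- with_stream_seed(
    config$seed + 1L,
    simulate_measurements(patients, config)
  )
  medications <- with_stream_seed(
    config$seed + 2L,
    simulate_medications(patients, config)
  )

  # a department guarantees a measurement inside the 48 h delta window when
  # the rise time plus the widest sampling gap fits inside that window
  delta_window_ok <- .hours(config$aki_profile$rise_hours) +
    1.3 * .days(config$cadence_days[patients$department]) <=
    .hours(rule_config$delta_window_hours)
  truth <- patients %>%
    mutate(delta_window_ok = unname(delta_window_ok)) %>%
    filter(.data$has_aki) %>%
    mutate(
      event_time = .data$anchor,
      fold_change = config$aki_profile$fold_change,
      delta = .data$baseline * (config$aki_profile$fold_change - 1),
      detectable = .data$fold_change >= rule_config$ratio_threshold |
        (.data$delta >= rule_config$delta_threshold & .data$delta_window_ok)
    ) %>%
    select(
      "patient_id", "event_time", "fold_change", "delta", "detectable"
    )

  demographics <- patients %>%
    select(
      "patient_id", "birth_date", "sex",
      "icu_flag", "covid_flag", "dialysis_flag"
    )

  structure(
    list(
      measurements = measurements,
      medications = medications,
      demographics = demographics,
      truth = truth,
      nephro_list = config$nephro_drugs,
      config = config
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n")
  cat(sprintf(
    "  %d patients, %d measurements, %d medication records, %d injected events\n",
    nrow(x$demographics), nrow(x$measurements), nrow(x$medications),
    nrow(x$truth)
  ))
  invisible(x)
}

# patient-level frame: demographics plus latent event parameters
simulate_patients <- function(config) {
  per <- config$periods
  rows <- list()
  offset <- 0L
  for (pi in seq_len(nrow(per))) {
    period <- per$period[pi]
    n <- config$n_patients[[period]]
    if (n == 0L) next
    id <- sprintf("P%06d", offset + seq_len(n))
    offset <- offset + n
    sex <- ifelse(runif(n) < config$p_female, "female", "male")
    age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 18), 95)
    dept <- sample(
      names(config$department_mix), n,
      replace = TRUE, prob = config$department_mix
    )
    is_icu <- runif(n) < config$p_icu
    dept[is_icu] <- "ICU"
    bl_par <- config$baseline_creatinine
    baseline <- exp(rnorm(
      n,
      mean = ifelse(sex == "female", bl_par$female[["meanlog"]], bl_par$male[["meanlog"]]),
      sd = ifelse(sex == "female", bl_par$female[["sdlog"]], bl_par$male[["sdlog"]])
    ))
    span <- as.numeric(per$end[pi]) - as.numeric(per$start[pi])
    anchor <- as.POSIXct(
      as.numeric(per$start[pi]) + runif(n, 0, span - 1),
      origin = "1970-01-01", tz = "UTC"
    )
    specialty <- sample(
      c(
        "internal_medicine", "surgery", "cardiology",
        "oncology", "geriatrics", "emergency_medicine"
      ),
      n,
      replace = TRUE, prob = c(0.30, 0.20, 0.15, 0.15, 0.10, 0.10)
    )
    rows[[pi]] <- tibble(
      patient_id = id,
      period = period,
      sex = sex,
      age_years = age,
      birth_date = as.Date(anchor) - round(age * 365.25),
      department = dept,
      specialty = specialty,
      baseline = baseline,
      anchor = anchor,
      has_aki = runif(n) < config$aki_event_rate,
      icu_flag = dept == "ICU",
      covid_flag = runif(n) < config$p_covid_cohort,
      dialysis_flag = FALSE
    )
  }
  bind_rows(rows)
}

# latent creatinine at offset dt (seconds) from the event anchor
latent_value <- function(baseline, fold, dt, recovery_days) {
  peak_hold <- 86400 # elevated plateau for one day after the event
  if (dt < 0) {
    baseline
  } else if (dt <= peak_hold) {
    baseline * fold
  } else {
    frac <- min(1, (dt - peak_hold) / .days(recovery_days))
    baseline * fold^(1 - frac)
  }
}

simulate_measurements <- function(patients, config) {
  prof <- config$aki_profile
  rows <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    dept <- p$department
    cad <- .days(config$cadence_days[[dept]])
    nh <- config$n_history[[dept]]
    a <- as.numeric(p$anchor)
    # pre-anchor history: normal-range values ending >= rise_hours before
    # the anchor so the rise itself is never sampled mid-flight
    gaps <- cad * runif(nh, 0.7, 1.3)
    t_hist <- a - .hours(prof$rise_hours) - cumsum(gaps)
    times <- sort(t_hist)
    dts <- times - a
    lat <- vapply(
      dts, function(dt) latent_value(p$baseline, 1, dt, prof$recovery_days),
      numeric(1)
    )
    # anchor measurement (the injected event when has_aki)
    fold <- if (p$has_aki) prof$fold_change else 1
    times <- c(times, a)
    lat <- c(lat, p$baseline * fold)
    if (p$has_aki) {
      if (runif(1) < config$p_followup[[p$period]]) {
        t_fu <- a + .hours(runif(1, 6, 42))
        times <- c(times, t_fu)
        lat <- c(lat, latent_value(p$baseline, fold, t_fu - a, prof$recovery_days))
      } else if (runif(1) < 0.6) {
        # a late measurement well outside the 2-day follow-up window
        t_late <- a + .days(runif(1, 3, 10))
        times <- c(times, t_late)
        lat <- c(lat, latent_value(p$baseline, fold, t_late - a, prof$recovery_days))
      }
    } else if (runif(1) < 0.3) {
      t_later <- a + .days(runif(1, 1, 5))
      times <- c(times, t_later)
      lat <- c(lat, p$baseline)
    }
    noise <- if (config$noise_sd > 0) {
      exp(rnorm(length(lat), 0, config$noise_sd))
    } else {
      rep(1, length(lat))
    }
    rows[[i]] <- tibble(
      patient_id = p$patient_id,
      timestamp = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
      creatinine_umol_l = round(lat * noise, 1),
      department = dept,
      specialty = p$specialty
    )
  }
  bind_rows(rows) %>% arrange(.data$patient_id, .data$timestamp)
}

simulate_medications <- function(patients, config) {
  rows <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    a <- as.numeric(p$anchor)
    recs <- list()
    if (runif(1) < config$p_nephro_use[[p$period]]) {
      start <- a - .days(runif(1, 1, 30))
      stop <- if (runif(1) < config$p_stop[[p$period]]) {
        a + .days(runif(1, 0.1, 7))
      } else if (runif(1) < 0.5) {
        a + .days(runif(1, 8, 30))
      } else {
        NA_real_
      }
      recs[[1]] <- tibble(
        patient_id = p$patient_id,
        drug_id = sample(config$nephro_drugs, 1),
        start = start, stop = stop
      )
    }
    if (runif(1) < 0.5) {
      recs[[length(recs) + 1L]] <- tibble(
        patient_id = p$patient_id,
        drug_id = sample(config$other_drugs, 1),
        start = a - .days(runif(1, 1, 60)),
        stop = if (runif(1) < 0.5) a + .days(runif(1, 1, 30)) else NA_real_
      )
    }
    if (length(recs) > 0L) rows[[i]] <- bind_rows(recs)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(
      patient_id = character(), drug_id = character(),
      start = as.POSIXct(character(), tz = "UTC"),
      stop = as.POSIXct(character(), tz = "UTC")
    ))
  }
  out %>%
    mutate(
      start = as.POSIXct(.data$start, origin = "1970-01-01", tz = "UTC"),
      stop = as.POSIXct(.data$stop, origin = "1970-01-01", tz = "UTC")
    ) %>%
    arrange(.data$patient_id, .data$start)
}

#' Match detector alerts against the injected-event truth log
#'
#' Each injected event is matched to the nearest positive alert of the
#' same patient within the tolerance window. Sensitivity is reported over
#' the events flagged detectable by construction; positive alerts not
#' matched to any event are counted as false alerts per patient.
#'
#' @param alerts Alert tibble from [detect_alerts()] run on the simulated
#'   cohort.
#' @param truth Truth log from [simulate_cohort()].
#' @param tolerance_hours Maximum |alert time - event time| for a match.
#' @return A list: `matches` (truth with `matched`, `alert_time`),
#'   `sensitivity` (detectable events), `sensitivity_all`,
#'   `false_alerts_per_patient` (tibble), `n_false_alerts`.
#' @export
truth_match <- function(alerts, truth, tolerance_hours = 48) {
  pos <- alerts[alerts$outcome == "positive", , drop = FALSE]
  tol <- .hours(tolerance_hours)
  pos_by_pat <- split(as.numeric(pos$timestamp), pos$patient_id)

  n <- nrow(truth)
  matched <- logical(n)
  alert_time <- rep(NA_real_, n)
  matched_alert_key <- character(0)
  et <- as.numeric(.as_utc(truth$event_time))
  for (i in seq_len(n)) {
    at <- pos_by_pat[[truth$patient_id[i]]]
    if (is.null(at)) next
    d <- abs(at - et[i])
    j <- which.min(d)
    if (d[j] <= tol) {
      matched[i] <- TRUE
      alert_time[i] <- at[j]
      matched_alert_key <- c(
        matched_alert_key,
        paste(truth$patient_id[i], at[d <= tol])
      )
    }
  }
  pos_key <- paste(pos$patient_id, as.numeric(pos$timestamp))
  false_pos <- pos[!pos_key %in% matched_alert_key, , drop = FALSE]
  fp_counts <- false_pos %>%
    group_by(.data$patient_id) %>%
    summarise(n_false = dplyr::n(), .groups = "drop")

  list(
    matches = truth %>% mutate(
      matched = matched,
      alert_time = as.POSIXct(alert_time, origin = "1970-01-01", tz = "UTC")
    ),
    sensitivity = if (any(truth$detectable)) {
      mean(matched[truth$detectable])
    } else {
      NA_real_
    },
    sensitivity_all = if (n > 0) mean(matched) else NA_real_,
    false_alerts_per_patient = fp_counts,
    n_false_alerts = nrow(false_pos)
  )
}
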
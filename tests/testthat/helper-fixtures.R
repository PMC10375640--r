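# fixture builders and independent brute-force oracles

T0 <- as.POSIXct("2021-06-15 12:00:00", tz = "UTC")

at_hours <- function(h) T0 + h * 3600
at_days <- function(d) T0 + d * 86400

make_measurements <- function(hours, values, patient_id = "P1",
                              department = "ward",
                              specialty = "internal_medicine") {
  tibble::tibble(
    patient_id = patient_id,
    timestamp = at_hours(hours),
    creatinine_umol_l = values,
    department = department,
    specialty = specialty
  )
}

make_demographics <- function(patient_id = "P1", birth_date = as.Date("1960-01-01"),
                              sex = "male", icu_flag = FALSE, covid_flag = FALSE,
                              dialysis_flag = FALSE) {
  tibble::tibble(
    patient_id = patient_id, birth_date = birth_date, sex = sex,
    icu_flag = icu_flag, covid_flag = covid_flag, dialysis_flag = dialysis_flag
  )
}

# --- brute-force oracles -------------------------------------------------
# exhaustive candidate scans, written independently of the package kernels

oracle_baseline <- function(times, values, index_time,
                            bw_days = 7, fw_days = 365) {
  it <- as.numeric(index_time)
  t <- as.numeric(times)
  best_val <- Inf
  best_t <- NA_real_
  for (j in seq_along(t)) {
    if (t[j] > it - bw_days * 86400 && t[j] < it) {
      if (values[j] < best_val ||
        (values[j] == best_val && t[j] >= best_t)) {
        best_val <- values[j]
        best_t <- t[j]
      }
    }
  }
  if (is.finite(best_val)) {
    return(list(status = "found_7d", value = best_val, time = best_t))
  }
  recent_t <- -Inf
  recent_val <- NA_real_
  for (j in seq_along(t)) {
    if (t[j] >= it - fw_days * 86400 && t[j] <= it - bw_days * 86400) {
      if (t[j] >= recent_t) {
        recent_t <- t[j]
        recent_val <- values[j]
      }
    }
  }
  if (is.finite(recent_t)) {
    return(list(status = "found_365d", value = recent_val, time = recent_t))
  }
  list(status = "none", value = NA_real_, time = NA_real_)
}

oracle_delta <- function(times, values, index_time, index_value,
                         window_hours = 48, threshold = 26.5) {
  it <- as.numeric(index_time)
  t <- as.numeric(times)
  lo <- Inf
  for (j in seq_along(t)) {
    if (t[j] > it - window_hours * 3600 && t[j] < it && values[j] < lo) {
      lo <- values[j]
    }
  }
  if (!is.finite(lo)) {
    return(list(fired = FALSE, delta = NA_real_))
  }
  list(fired = (index_value - lo) >= threshold, delta = index_value - lo)
}

oracle_outcome <- function(times, values, index_time, index_value) {
  bl <- oracle_baseline(times, values, index_time)
  dl <- oracle_delta(times, values, index_time, index_value)
  in48 <- any(as.numeric(times) > as.numeric(index_time) - 48 * 3600 &
    as.numeric(times) < as.numeric(index_time))
  if (bl$status == "none" && !in48) {
    return("unable_to_compute")
  }
  ratio_fired <- bl$status != "none" && index_value / bl$value >= 1.5
  if (dl$fired || ratio_fired) "positive" else "negative"
}

# random one-patient series: irregular timestamps over ~400 days, values
# spanning normal to clearly pathological creatinine
random_series <- function(n_meas, patient_id = "P1") {
  hours <- sort(runif(n_meas, -400 * 24, 0))
  make_measurements(
    hours = hours,
    values = round(runif(n_meas, 40, 260), 1),
    patient_id = patient_id
  )
}

small_cohort <- function(n = 120L, seed = 303L, ...) {
  simulate_cohort(sim_config(
    n_patients = c(before = n, after = n), seed = seed, ...
  ))
}
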
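#' Creatinine follow-up within the 2-day window
#'
#' @param start_time Episode start (POSIXct), i.e. the first positive
#'   alert's measurement time.
#' @param measurement_times POSIXct times of the patient's full creatinine
#'   series.
#' @param config An [aki_config()]; the window is
#'   `(start, start + followup_window_hours]`.
#' @return `TRUE` when at least one measurement falls in the window.
#' @export
followup_within_2days <- function(start_time, measurement_times,
                                  config = aki_config()) {
  t0 <- as.numeric(.as_utc(start_time))
  t <- as.numeric(.as_utc(measurement_times))
  any(t > t0 & t <= t0 + .hours(config$followup_window_hours))
}

#' Nephrotoxic exposure at episode start
#'
#' A patient is "on nephrotoxic medication" when at least one record whose
#' drug is on the nephrotoxic list spans the episode start: the exposure
#' interval is `[start, stop)`, with a missing stop meaning ongoing.
#'
#' @param start_time Episode start (POSIXct).
#' @param medications Tibble with `drug_id`, `start`, `stop` (POSIXct,
#'   `stop` may be `NA`) for one patient.
#' @param nephro_list Character vector of nephrotoxic drug identifiers
#'   (must be non-empty).
#' @return Logical.
#' @export
on_nephrotoxic <- function(start_time, medications, nephro_list) {
  if (length(nephro_list) == 0L) {
    abort("the nephrotoxic drug list is empty; check configuration")
  }
  n_active_nephro(start_time, medications, nephro_list) > 0L
}

n_active_nephro <- function(start_time, medications, nephro_list) {
  t0 <- as.numeric(.as_utc(start_time))
  ms <- as.numeric(.as_utc(medications$start))
  me <- as.numeric(.as_utc(medications$stop))
  sum(medications$drug_id %in% nephro_list &
    ms <= t0 & (is.na(me) | me > t0))
}

# stop times (numeric seconds) of nephrotoxic records active at start_time
active_nephro_stops <- function(start_time, medications, nephro_list) {
  t0 <- as.numeric(.as_utc(start_time))
  ms <- as.numeric(.as_utc(medications$start))
  me <- as.numeric(.as_utc(medications$stop))
  act <- medications$drug_id %in% nephro_list &
    ms <= t0 & (is.na(me) | me > t0)
  me[act]
}

#' Nephrotoxic discontinuation within the 7-day window
#'
#' Among nephrotoxic records active at episode start, is at least one
#' stopped within `(start, start + stop_window_days]`? Only call when
#' [on_nephrotoxic()] is `TRUE`; episodes without nephrotoxic exposure are
#' excluded from this endpoint.
#'
#' @inheritParams on_nephrotoxic
#' @param config An [aki_config()].
#' @return Logical.
#' @export
stop_within_7days <- function(start_time, medications, nephro_list,
                              config = aki_config()) {
  if (n_active_nephro(start_time, medications, nephro_list) == 0L) {
    abort("stop_within_7days() requires nephrotoxic exposure at episode start")
  }
  t0 <- as.numeric(.as_utc(start_time))
  stops <- active_nephro_stops(start_time, medications, nephro_list)
  any(!is.na(stops) & stops > t0 & stops <= t0 + .days(config$stop_window_days))
}

#' Awareness endpoints for every episode
#'
#' Assigns each episode to the before/after period by its start time and
#' computes the two awareness endpoints: a creatinine follow-up
#' measurement within 2 days, and — for episodes with nephrotoxic exposure
#' at start — discontinuation of at least one nephrotoxic medication
#' within 7 days (`NA` for unexposed episodes, which the stop endpoint
#' excludes by design).
#'
#' @param episodes Episode tibble from [segment_episodes()] (typically
#'   after [filter_analysis_population()]).
#' @param measurements Full measurement tibble (used for follow-up).
#' @param medications Medication tibble: `patient_id`, `drug_id`, `start`,
#'   `stop`.
#' @param nephro_list Character vector of nephrotoxic drug ids.
#' @param demographics Optional demographics tibble; contributes `sex` for
#'   stratification.
#' @param config An [aki_config()]; supplies windows and period table.
#' @return `episodes` plus `period` (`NA` outside both periods),
#'   `followup_2d`, `on_nephrotoxic`, `stop_within_7d`, and `sex` when
#'   demographics are given.
#' @export
episode_outcomes <- function(episodes, measurements, medications, nephro_list,
                             demographics = NULL, config = aki_config()) {
  ep <- episodes
  ep$period <- assign_period(ep$start_time, config$periods)

  meas_by_pat <- split(
    as.numeric(.as_utc(measurements$timestamp)),
    measurements$patient_id
  )
  med_by_pat <- split(
    medications[, c("drug_id", "start", "stop")],
    medications$patient_id
  )
  empty_med <- tibble(
    drug_id = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    stop = as.POSIXct(character(), tz = "UTC")
  )

  t0 <- as.numeric(.as_utc(ep$start_time))
  fw <- .hours(config$followup_window_hours)
  n <- nrow(ep)
  followup <- logical(n)
  on_neph <- logical(n)
  stopped <- rep(NA, n)
  for (i in seq_len(n)) {
    mt <- meas_by_pat[[ep$patient_id[i]]]
    followup[i] <- !is.null(mt) && any(mt > t0[i] & mt <= t0[i] + fw)
    md <- med_by_pat[[ep$patient_id[i]]]
    if (is.null(md)) md <- empty_med
    on_neph[i] <- n_active_nephro(ep$start_time[i], md, nephro_list) > 0L
    if (on_neph[i]) {
      stopped[i] <- stop_within_7days(ep$start_time[i], md, nephro_list, config)
    }
  }
  ep$followup_2d <- followup
  ep$on_nephrotoxic <- on_neph
  ep$stop_within_7d <- stopped
  if (!is.null(demographics) && "sex" %in% names(demographics)) {
    ep <- left_join(
      ep, demographics[, c("patient_id", "sex")],
      by = "patient_id"
    )
  }
  ep
}

assign_period <- function(times, periods) {
  t <- as.numeric(.as_utc(times))
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(periods))) {
    sel <- t >= as.numeric(periods$start[i]) & t < as.numeric(periods$end[i])
    out[sel] <- periods$period[i]
  }
  out
}

#' Two-by-two comparison from counts
#'
#' Builds the period-by-outcome table and tests equality of the two
#' proportions with Pearson's chi-square, by default with the Yates
#' continuity correction (which subtracts N/2 from |ad - bc| and clamps
#' the statistic at zero). Degenerate tables — an empty period or an
#' outcome margin of zero — carry `NA` statistics and a flag rather than
#' an error.
#'
#' @param x_before,n_before Numerator and denominator in the before
#'   period.
#' @param x_after,n_after Numerator and denominator in the after period.
#' @param correct Apply the continuity correction.
#' @return An object of class `aki_2x2`: counts, proportions, `chi2`,
#'   `p_value`, `degenerate`.
#' @export
two_by_two <- function(x_before, n_before, x_after, n_after, correct = TRUE) {
  stopifnot(
    x_before >= 0, x_after >= 0,
    x_before <= n_before, x_after <= n_after
  )
  counts <- matrix(
    c(x_before, n_before - x_before, x_after, n_after - x_after),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("before", "after"), c("yes", "no"))
  )
  degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  if (degenerate) {
    chi2 <- NA_real_
    p <- NA_real_
  } else {
    ht <- suppressWarnings(chisq.test(counts, correct = correct))
    chi2 <- unname(ht$statistic)
    p <- unname(ht$p.value)
  }
  structure(
    list(
      counts = counts,
      x = c(before = x_before, after = x_after),
      n = c(before = n_before, after = n_after),
      proportions = c(
        before = if (n_before > 0) x_before / n_before else NA_real_,
        after = if (n_after > 0) x_after / n_after else NA_real_
      ),
      chi2 = chi2, p_value = p, correction = correct,
      degenerate = degenerate
    ),
    class = "aki_2x2"
  )
}

#' @export
print.aki_2x2 <- function(x, ...) {
  cat("<aki_2x2>", if (x$correction) "(Yates-corrected)" else "(uncorrected)", "\n")
  cat(sprintf(
    "  before: %d/%d (%s%%)   after: %d/%d (%s%%)\n",
    x$x[["before"]], x$n[["before"]],
    format_percent(x$x[["before"]], x$n[["before"]]),
    x$x[["after"]], x$n[["after"]],
    format_percent(x$x[["after"]], x$n[["after"]])
  ))
  if (x$degenerate) {
    cat("  degenerate table: no test performed\n")
  } else {
    cat(sprintf(
      "  chi2 = %.4f, p = %s\n", x$chi2, format_p_value(x$p_value)
    ))
  }
  invisible(x)
}

#' Compare an endpoint between the before and after periods
#'
#' @param outcomes Tibble from [episode_outcomes()], optionally
#'   pre-filtered to a stratum.
#' @param endpoint `"followup_2d"` or `"stop_within_7d"`. The stop
#'   endpoint restricts the denominators to episodes with nephrotoxic
#'   exposure at start.
#' @param correct Apply the Yates continuity correction.
#' @return An `aki_2x2` object.
#' @export
compare_periods <- function(outcomes,
                            endpoint = c("followup_2d", "stop_within_7d"),
                            correct = TRUE) {
  endpoint <- match.arg(endpoint)
  o <- outcomes[!is.na(outcomes$period), , drop = FALSE]
  if (endpoint == "stop_within_7d") {
    o <- o[o$on_nephrotoxic, , drop = FALSE]
  }
  y <- o[[endpoint]]
  two_by_two(
    x_before = sum(y[o$period == "before"]),
    n_before = sum(o$period == "before"),
    x_after = sum(y[o$period == "after"]),
    n_after = sum(o$period == "after"),
    correct = correct
  )
}

#' Stratified before-after endpoint report
#'
#' One row per endpoint for the overall population and for each level of
#' the requested strata (department, specialty, sex), mirroring the
#' layout of a before-after summary table: numerators, denominators,
#' percentages to one decimal, the corrected chi-square and its p-value.
#' Strata absent from one period yield a degenerate row, not an error.
#'
#' @param outcomes Tibble from [episode_outcomes()].
#' @param strata Character vector drawn from the columns of `outcomes`;
#'   defaults to department, specialty and (when present) sex. Unknown
#'   names are an error.
#' @param endpoints Endpoints to tabulate.
#' @param correct Apply the Yates continuity correction.
#' @return A tibble with columns `endpoint`, `stratum`, `level`,
#'   `x_before`, `n_before`, `pct_before`, `x_after`, `n_after`,
#'   `pct_after`, `chi2`, `p_value`, `p_label`, `degenerate`.
#' @export
stratified_report <- function(outcomes,
                              strata = intersect(
                                c("start_department", "start_specialty", "sex"),
                                names(outcomes)
                              ),
                              endpoints = c("followup_2d", "stop_within_7d"),
                              correct = TRUE) {
  unknown <- setdiff(strata, names(outcomes))
  if (length(unknown) > 0L) {
    abort(paste0(
      "unknown stratum column(s): ", paste(unknown, collapse = ", ")
    ))
  }
  rows <- list()
  for (ep in endpoints) {
    rows[[length(rows) + 1L]] <-
      report_row(outcomes, ep, "overall", "overall", correct)
    for (st in strata) {
      lv <- outcomes[[st]]
      for (level in sort(unique(lv[!is.na(lv)]))) {
        rows[[length(rows) + 1L]] <- report_row(
          outcomes[!is.na(lv) & lv == level, , drop = FALSE],
          ep, st, level, correct
        )
      }
    }
  }
  bind_rows(rows)
}

report_row <- function(outcomes, endpoint, stratum, level, correct) {
  r <- compare_periods(outcomes, endpoint, correct = correct)
  tibble(
    endpoint = endpoint, stratum = stratum, level = level,
    x_before = unname(r$x[["before"]]), n_before = unname(r$n[["before"]]),
    pct_before = format_percent(r$x[["before"]], r$n[["before"]]),
    x_after = unname(r$x[["after"]]), n_after = unname(r$n[["after"]]),
    pct_after = format_percent(r$x[["after"]], r$n[["after"]]),
    chi2 = r$chi2, p_value = r$p_value,
    p_label = format_p_value(r$p_value),
    degenerate = r$degenerate
  )
}

#' Share of alerts computed from a 7-day baseline
#'
#' Among triggering alerts that have a baseline, the fraction whose
#' baseline came from the 7-day window rather than the 365-day fallback —
#' a check on how often the fallback (which risks stale baselines) is
#' actually exercised.
#'
#' @param alerts Alert tibble from [detect_alerts()].
#' @return A list: `n_7d`, `n_total`, `fraction`, `percent` (1-decimal
#'   string); `fraction` is `NA` when no alert qualifies.
#' @export
baseline_window_share <- function(alerts) {
  a <- alerts[alerts$outcome != "negative" &
    alerts$baseline_status != "none", , drop = FALSE]
  n_total <- nrow(a)
  n_7d <- sum(a$baseline_status == "found_7d")
  list(
    n_7d = n_7d,
    n_total = n_total,
    fraction = if (n_total > 0) n_7d / n_total else NA_real_,
    percent = if (n_total > 0) format_percent(n_7d, n_total) else NA_character_
  )
}

#' Percentage formatter (one decimal)
#'
#' @param x,n Numerator and denominator.
#' @return Character, e.g. `"56.6"` for 500/884.
#' @export
format_percent <- function(x, n) {
  ifelse(n > 0, sprintf("%.1f", 100 * x / n), NA_character_)
}

#' P-value formatter
#'
#' Three decimals; values below 0.001 print as `"<0.001"`; values that
#' round to one print as `"1.0"`.
#'
#' @param p Numeric p-value(s) in `[0, 1]` (NA allowed).
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) {
      NA_character_
    } else if (pi < 0.001) {
      "<0.001"
    } else if (round(pi, 3) >= 1) {
      "1.0"
    } else {
      sprintf("%.3f", pi)
    }
  }, character(1))
}
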
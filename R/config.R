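#' Study period boundaries
#'
#' Default six-month before/after windows around the alert go-live date.
#' Intervals are half-open: an episode belongs to a period when its start
#' time falls in `[start, end)`.
#'
#' @param before_start,before_end,after_start,after_end Period boundaries,
#'   coercible to POSIXct (UTC).
#' @return A tibble with columns `period`, `start`, `end`.
#' @export
default_periods <- function(before_start = "2021-04-06",
                            before_end = "2021-10-06",
                            after_start = "2021-10-06",
                            after_end = "2022-04-06") {
  p <- tibble(
    period = c("before", "after"),
    start = .as_utc(c(before_start, after_start)),
    end = .as_utc(c(before_end, after_end))
  )
  if (any(p$end <= p$start)) {
    abort("each period must have end > start")
  }
  if (p$start[2] < p$end[1]) {
    abort("before and after periods must not overlap")
  }
  p
}

#' Rule-engine and evaluation configuration
#'
#' Bundles every tunable of the alerting pipeline: the two KDIGO stage-1
#' creatinine criteria (absolute delta and fold-change over baseline), the
#' look-back windows, the notification policy, and the endpoint windows of
#' the before-after evaluation. Defaults are the deployed rule set:
#' 26.5 umol/L within 48 h, 1.5x a 7-day minimum baseline with a 365-day
#' most-recent fallback, 7-day episode and phone-suppression windows, and
#' Yates-corrected chi-square comparisons.
#'
#' Look-back windows are half-open towards the index measurement so a value
#' can never serve as its own baseline: the delta window is `(t - 48 h, t)`,
#' the baseline window `(t - 7 d, t)` and the fallback window
#' `[t - 365 d, t - 7 d]`. Threshold comparisons are inclusive (`>=`).
#'
#' @param delta_threshold Absolute creatinine increase, umol/L.
#' @param ratio_threshold Fold-change over baseline (dimensionless).
#' @param delta_window_hours Look-back for the absolute-increase criterion.
#' @param baseline_window_days Look-back over which the minimum value is the
#'   baseline.
#' @param fallback_window_days Maximum look-back for the most-recent-value
#'   fallback baseline.
#' @param episode_window_days Alerts within this many days of an episode's
#'   first alert belong to that episode (anchored window).
#' @param phone_suppression_days A positive alert is not phoned when a
#'   phoned alert occurred within this window, unless a non-triggering
#'   measurement intervened.
#' @param adult_age_years Minimum age (inclusive) for the alert to be
#'   displayed.
#' @param dialysis_departments,icu_departments Department codes treated as
#'   dialysis / intensive care.
#' @param phone_excluded_departments Departments never phoned (the alert is
#'   still displayed outside dialysis).
#' @param followup_window_hours Window after episode start for the
#'   creatinine follow-up endpoint.
#' @param stop_window_days Window after episode start for the nephrotoxic
#'   discontinuation endpoint.
#' @param continuity_correction Use the Yates continuity correction in
#'   period comparisons.
#' @param periods Period table as produced by [default_periods()].
#' @return An object of class `aki_config`.
#' @export
aki_config <- function(delta_threshold = 26.5,
                       ratio_threshold = 1.5,
                       delta_window_hours = 48,
                       baseline_window_days = 7,
                       fallback_window_days = 365,
                       episode_window_days = 7,
                       phone_suppression_days = 7,
                       adult_age_years = 18,
                       dialysis_departments = "dialysis",
                       icu_departments = "ICU",
                       phone_excluded_departments = c("dialysis", "ICU", "COVID_ward"),
                       followup_window_hours = 48,
                       stop_window_days = 7,
                       continuity_correction = TRUE,
                       periods = default_periods()) {
  num_pos <- c(
    delta_threshold = delta_threshold, ratio_threshold = ratio_threshold,
    delta_window_hours = delta_window_hours,
    baseline_window_days = baseline_window_days,
    fallback_window_days = fallback_window_days,
    episode_window_days = episode_window_days,
    followup_window_hours = followup_window_hours,
    stop_window_days = stop_window_days
  )
  bad <- !is.finite(num_pos) | num_pos <= 0
  if (any(bad)) {
    abort(paste0(
      "configuration values must be positive: ",
      paste(names(num_pos)[bad], collapse = ", ")
    ))
  }
  if (phone_suppression_days < 0) abort("phone_suppression_days must be >= 0")
  if (fallback_window_days <= baseline_window_days) {
    abort("fallback_window_days must exceed baseline_window_days")
  }
  structure(
    list(
      delta_threshold = delta_threshold,
      ratio_threshold = ratio_threshold,
      delta_window_hours = delta_window_hours,
      baseline_window_days = baseline_window_days,
      fallback_window_days = fallback_window_days,
      episode_window_days = episode_window_days,
      phone_suppression_days = phone_suppression_days,
      adult_age_years = adult_age_years,
      dialysis_departments = dialysis_departments,
      icu_departments = icu_departments,
      phone_excluded_departments = phone_excluded_departments,
      followup_window_hours = followup_window_hours,
      stop_window_days = stop_window_days,
      continuity_correction = continuity_correction,
      periods = periods
    ),
    class = "aki_config"
  )
}

#' @export
print.aki_config <- function(x, ...) {
  cat("<aki_config>\n")
  cat(sprintf(
    "  criteria: delta >= %.1f umol/L in %g h  |  ratio >= %.2f x baseline\n",
    x$delta_threshold, x$delta_window_hours, x$ratio_threshold
  ))
  cat(sprintf(
    "  baseline: min over %g d, fallback most recent in %g-%g d\n",
    x$baseline_window_days, x$baseline_window_days, x$fallback_window_days
  ))
  cat(sprintf(
    "  episodes: %g d anchored window; phone suppression %g d\n",
    x$episode_window_days, x$phone_suppression_days
  ))
  cat(sprintf(
    "  endpoints: follow-up %g h, medication stop %g d, Yates correction %s\n",
    x$followup_window_hours, x$stop_window_days, x$continuity_correction
  ))
  invisible(x)
}
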
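#' Run the full e-alert pipeline
#'
#' Detection, notification policy, episode segmentation, analysis-
#' population filtering and the before-after endpoint evaluation, in
#' order, with stage counts logged the way a deployment report would
#' state them (alerts by outcome, episodes, exclusions, analysable
#' episodes per period). An empty analysis population completes with a
#' degenerate report and a warning rather than an error.
#'
#' @param measurements,demographics,medications Validated input tibbles
#'   (see [validate_inputs()] or the readers).
#' @param nephro_list Character vector of nephrotoxic drug identifiers.
#' @param config An [aki_config()].
#' @param output_dir Optional directory; when given, writes `alerts.csv`,
#'   `episodes.csv`, `outcomes.csv`, `report.csv` (long form: one row per
#'   period, stratum and endpoint) and a human-readable `summary.txt`.
#' @param quiet Suppress stage-count messages.
#' @return A list of class `aki_pipeline`: `alerts`, `episodes`,
#'   `exclusions`, `outcomes`, `report`, `baseline_share`, `config`.
#' @export
run_pipeline <- function(measurements, demographics, medications, nephro_list,
                         config = aki_config(), output_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))

  say("detect: %d measurements from %d patients", nrow(measurements),
    length(unique(measurements$patient_id)))
  alerts <- detect_alerts(measurements, demographics, config)
  tab <- table(alerts$outcome)
  say(
    "detect: %d positive, %d negative, %d unable-to-compute",
    tab["positive"] %|0|% 0, tab["negative"] %|0|% 0,
    tab["unable_to_compute"] %|0|% 0
  )
  alerts <- phone_decisions(alerts, config)
  say("notify: %d alerts phoned, %d displayed", sum(alerts$phone),
    sum(alerts$display))

  episodes <- segment_episodes(alerts, config)
  say("episodes: %d episodes from %d positive alerts", nrow(episodes),
    sum(alerts$outcome == "positive"))

  filt <- filter_analysis_population(episodes, demographics, config = config)
  say(
    "analysis population: %d episodes retained, %d excluded (%s)",
    nrow(filt$episodes), filt$n_excluded,
    paste(sprintf("%s: %d", filt$exclusions$reason, filt$exclusions$n),
      collapse = ", "
    )
  )

  outcomes <- episode_outcomes(
    filt$episodes, measurements, medications, nephro_list,
    demographics = demographics, config = config
  )
  n_per <- table(factor(outcomes$period, levels = c("before", "after")))
  say(
    "evaluation: %d before / %d after episodes (%d outside both periods)",
    n_per[["before"]], n_per[["after"]], sum(is.na(outcomes$period))
  )
  if (sum(!is.na(outcomes$period)) == 0L) {
    warn("analysis population is empty; the report is degenerate")
  }

  report <- stratified_report(outcomes, correct = config$continuity_correction)
  share <- baseline_window_share(alerts)

  result <- structure(
    list(
      alerts = alerts, episodes = episodes, exclusions = filt$exclusions,
      outcomes = outcomes, report = report, baseline_share = share,
      config = config
    ),
    class = "aki_pipeline"
  )
  if (!is.null(output_dir)) {
    write_pipeline_outputs(result, output_dir)
  }
  result
}

`%|0|%` <- function(x, y) if (is.na(x)) y else x

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$alerts, file.path(dir, "alerts.csv"))
  readr::write_csv(
    result$episodes %>%
      select(
        "patient_id",
        episode_start = "start_time",
        department = "start_department",
        specialty = "start_specialty",
        "n_alerts"
      ),
    file.path(dir, "episodes.csv")
  )
  readr::write_csv(result$outcomes, file.path(dir, "outcomes.csv"))
  readr::write_csv(report_long(result$report), file.path(dir, "report.csv"))
  writeLines(summary_text(result), file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Long-form machine-readable report
#'
#' Reshapes the wide [stratified_report()] table to one row per period,
#' stratum and endpoint — the layout written to `report.csv`.
#'
#' @param report A tibble from [stratified_report()].
#' @return A tibble with columns `period`, `stratum`, `level`, `endpoint`,
#'   `numerator`, `denominator`, `percent`, `chi2`, `p`.
#' @export
report_long <- function(report) {
  before <- report %>%
    mutate(
      period = "before", numerator = .data$x_before,
      denominator = .data$n_before, percent = .data$pct_before
    )
  after <- report %>%
    mutate(
      period = "after", numerator = .data$x_after,
      denominator = .data$n_after, percent = .data$pct_after
    )
  bind_rows(before, after) %>%
    select(
      "period", "stratum", "level", "endpoint",
      "numerator", "denominator", "percent", "chi2",
      p = "p_value"
    ) %>%
    arrange(.data$endpoint, .data$stratum, .data$level, dplyr::desc(.data$period))
}

#' Human-readable before-after summary
#'
#' @param result An `aki_pipeline` result.
#' @return Character vector of report lines.
#' @export
summary_text <- function(result) {
  r <- result$report
  lines <- c(
    "AKI e-alert before-after evaluation",
    sprintf(
      "7-day baselines among triggering alerts: %s of %s (%s%%)",
      result$baseline_share$n_7d, result$baseline_share$n_total,
      result$baseline_share$percent %|0|% "-"
    ),
    ""
  )
  for (ep in unique(r$endpoint)) {
    label <- switch(ep,
      followup_2d = "PCr follow-up within 2 days",
      stop_within_7d = "Nephrotoxic medication stop within 7 days",
      ep
    )
    lines <- c(lines, label)
    sub <- r[r$endpoint == ep, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      lines <- c(lines, sprintf(
        "  %-18s %-20s %5d/%-5d (%s%%)  vs  %5d/%-5d (%s%%)   p = %s",
        row$stratum, row$level,
        row$x_before, row$n_before, row$pct_before %|0|% "-",
        row$x_after, row$n_after, row$pct_after %|0|% "-",
        row$p_label %|0|% "-"
      ))
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.aki_pipeline <- function(x, ...) {
  cat(summary_text(x), sep = "\n")
  invisible(x)
}
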
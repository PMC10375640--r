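meds <- function(drug, start_d, stop_d = NA_real_, patient_id = "P1") {
  tibble::tibble(
    patient_id = patient_id, drug_id = drug,
    start = at_days(start_d),
    stop = if (is.na(stop_d)) as.POSIXct(NA, tz = "UTC") else at_days(stop_d)
  )
}
NEPHRO <- c("gentamicin", "vancomycin")

test_that("2-day follow-up window is (start, start + 48 h]", {
  expect_true(followup_within_2days(T0, at_hours(36)))
  expect_false(followup_within_2days(T0, at_hours(49)))
  expect_true(followup_within_2days(T0, at_hours(48))) # closed right edge
  expect_false(followup_within_2days(T0, at_hours(0))) # the start itself
  expect_false(followup_within_2days(T0, at_hours(c(-30, -1))))
  expect_false(followup_within_2days(T0, as.POSIXct(character(), tz = "UTC")))
})

test_that("nephrotoxic exposure requires a listed drug active at episode start", {
  expect_true(on_nephrotoxic(T0, meds("gentamicin", -5, 3), NEPHRO))
  expect_true(on_nephrotoxic(T0, meds("gentamicin", -5, NA), NEPHRO)) # ongoing
  expect_false(on_nephrotoxic(T0, meds("gentamicin", -5, -1), NEPHRO)) # stopped before
  expect_false(on_nephrotoxic(T0, meds("paracetamol", -5, 3), NEPHRO)) # not listed
  expect_error(on_nephrotoxic(T0, meds("gentamicin", -5, 3), character()), "empty")
})

test_that("7-day stop endpoint needs one active nephrotoxic stopped in (start, start + 7 d]", {
  two <- dplyr::bind_rows(meds("gentamicin", -5, 3), meds("vancomycin", -10, NA))
  expect_true(stop_within_7days(T0, two, NEPHRO)) # one of two suffices
  expect_false(stop_within_7days(T0, meds("gentamicin", -5, 8), NEPHRO))
  expect_false(stop_within_7days(T0, meds("gentamicin", -5, NA), NEPHRO))
  expect_true(stop_within_7days(T0, meds("gentamicin", -5, 7), NEPHRO)) # boundary
  expect_error(
    stop_within_7days(T0, meds("paracetamol", -5, 3), NEPHRO),
    "exposure"
  )
})

test_that("corrected chi-square matches the textbook formula on random tables", {
  set.seed(77)
  for (rep in 1:60) {
    n1 <- sample(5:400, 1)
    n2 <- sample(5:400, 1)
    x1 <- rbinom(1, n1, runif(1, 0.05, 0.95))
    x2 <- rbinom(1, n2, runif(1, 0.05, 0.95))
    r <- two_by_two(x1, n1, x2, n2, correct = TRUE)
    if (r$degenerate) next
    # independent computation: N(|ad - bc| - N/2)^2 / (r1 r2 c1 c2),
    # clamped at zero when the correction exceeds |ad - bc|
    a <- as.numeric(x1); b <- as.numeric(n1 - x1)
    cc <- as.numeric(x2); d <- as.numeric(n2 - x2)
    N <- a + b + cc + d
    num <- max(0, abs(a * d - b * cc) - N / 2)
    stat <- N * num^2 / (n1 * n2 * (a + cc) * (b + d))
    expect_equal(r$chi2, stat, tolerance = 1e-10)
    expect_equal(r$p_value, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-10)
    # the correction is conservative
    expect_gte(r$p_value, two_by_two(x1, n1, x2, n2, correct = FALSE)$p_value)
    # proportions are the row ratios and label swap leaves p unchanged
    expect_equal(unname(r$proportions), c(x1 / n1, x2 / n2))
    expect_equal(two_by_two(x2, n2, x1, n1)$p_value, r$p_value)
  }
})

test_that("degenerate and no-effect tables are handled explicitly", {
  # identical tables in both periods: no evidence of change
  r <- two_by_two(50, 100, 50, 100)
  expect_equal(r$p_value, 1.0)
  # zero margins: flagged, not tested
  r <- two_by_two(0, 100, 0, 80)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
  r <- two_by_two(0, 0, 10, 20)
  expect_true(r$degenerate)
})

test_that("proportion and p-value formatting follow the reporting conventions", {
  expect_identical(format_percent(500, 884), "56.6")
  expect_identical(format_percent(442, 518), "85.3")
  expect_identical(format_percent(3189, 4023), "79.3")
  expect_true(is.na(format_percent(0, 0)))
  expect_identical(format_p_value(0.00311), "0.003")
  expect_identical(format_p_value(0.0002), "<0.001")
  expect_identical(format_p_value(0.99993), "1.0")
  expect_identical(format_p_value(0.3293), "0.329")
  expect_true(is.na(format_p_value(NA_real_)))
})

make_outcomes <- function(n_b, x_b, n_a, x_a, department = "ward", sex = "male") {
  tibble::tibble(
    episode_id = sprintf("E%d", seq_len(n_b + n_a)),
    patient_id = sprintf("P%d", seq_len(n_b + n_a)),
    start_department = department,
    start_specialty = "internal_medicine",
    sex = sex,
    period = rep(c("before", "after"), c(n_b, n_a)),
    followup_2d = c(
      rep(c(TRUE, FALSE), c(x_b, n_b - x_b)),
      rep(c(TRUE, FALSE), c(x_a, n_a - x_a))
    ),
    on_nephrotoxic = TRUE,
    stop_within_7d = FALSE
  )
}

test_that("stratified report mirrors the overall comparison for a single stratum", {
  oc <- make_outcomes(40, 25, 45, 35)
  rep_all <- stratified_report(oc, strata = "start_department")
  overall <- rep_all[rep_all$stratum == "overall" & rep_all$endpoint == "followup_2d", ]
  ward <- rep_all[rep_all$level == "ward" & rep_all$endpoint == "followup_2d", ]
  expect_equal(overall$p_value, ward$p_value)
  expect_equal(overall$x_before, ward$x_before)
  direct <- compare_periods(oc, "followup_2d")
  expect_equal(overall$p_value, direct$p_value)
  expect_equal(overall$chi2, direct$chi2)
})

test_that("a stratum absent in one period yields a degenerate flagged row", {
  oc <- make_outcomes(30, 10, 30, 15)
  oc$start_department[oc$period == "after"] <- "ED"
  r <- stratified_report(oc, strata = "start_department")
  ward <- r[r$level == "ward" & r$endpoint == "followup_2d", ]
  expect_true(ward$degenerate)
  expect_true(is.na(ward$p_value))
  expect_error(stratified_report(oc, strata = "florb"), "florb")
})

test_that("the stop endpoint excludes episodes without nephrotoxic exposure", {
  oc <- make_outcomes(20, 10, 20, 10)
  oc$on_nephrotoxic[1:5] <- FALSE
  oc$stop_within_7d[1:5] <- NA
  r <- compare_periods(oc, "stop_within_7d")
  expect_equal(unname(r$n[["before"]]), 15)
  expect_equal(unname(r$n[["after"]]), 20)
})

test_that("episode outcomes assign periods and endpoint flags per episode", {
  eps <- tibble::tibble(
    episode_id = c("P1/E1", "P2/E1", "P3/E1"),
    patient_id = c("P1", "P2", "P3"),
    start_time = c(
      as.POSIXct("2021-05-01 08:00", tz = "UTC"), # before period
      as.POSIXct("2021-12-01 08:00", tz = "UTC"), # after period
      as.POSIXct("2020-01-01 08:00", tz = "UTC") # outside both
    ),
    start_department = "ward", start_specialty = "internal_medicine",
    n_alerts = 1L
  )
  ms <- tibble::tibble(
    patient_id = "P1",
    timestamp = as.POSIXct("2021-05-02 08:00", tz = "UTC"),
    creatinine_umol_l = 100, department = "ward",
    specialty = "internal_medicine"
  )
  md <- meds("gentamicin", -1000, 1000, patient_id = "P2")
  oc <- episode_outcomes(eps, ms, md, NEPHRO,
    demographics = make_demographics(patient_id = c("P1", "P2", "P3"))
  )
  expect_equal(oc$period, c("before", "after", NA))
  expect_equal(oc$followup_2d, c(TRUE, FALSE, FALSE))
  expect_equal(oc$on_nephrotoxic, c(FALSE, TRUE, FALSE))
  expect_equal(oc$stop_within_7d, c(NA, FALSE, NA))
})

test_that("baseline-window share matches a direct recount", {
  co <- small_cohort(n = 80L)
  a <- detect_alerts(co$measurements, co$demographics)
  s <- baseline_window_share(a)
  trig <- a[a$outcome != "negative" & a$baseline_status != "none", ]
  expect_equal(s$n_total, nrow(trig))
  expect_equal(s$n_7d, sum(trig$baseline_status == "found_7d"))
  expect_equal(s$fraction, s$n_7d / s$n_total)
  # degenerate: no qualifying alerts
  expect_true(is.na(baseline_window_share(a[0, ])$fraction))
})
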
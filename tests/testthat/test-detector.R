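test_that("baseline selection follows the 7-day-minimum / 365-day-fallback rule", {
  # empty history: nothing to compare against
  empty <- make_measurements(numeric(0), numeric(0))
  expect_equal(select_baseline(empty, T0)$status, "none")

  # single candidate six days back
  one <- make_measurements(-6 * 24, 80)
  b <- select_baseline(one, T0)
  expect_equal(b$status, "found_7d")
  expect_equal(b$baseline_value, 80)

  # minimum over the 7-day window, not the most recent value
  h <- make_measurements(c(-10, -5, -2) * 24, c(90, 100, 70))
  b <- select_baseline(h, T0)
  expect_equal(b$status, "found_7d")
  expect_equal(b$baseline_value, 70)

  # fallback: most recent value between 365 and 7 days back
  h <- make_measurements(c(-400, -200, -30) * 24, c(90, 85, 95))
  b <- select_baseline(h, T0)
  expect_equal(b$status, "found_365d")
  expect_equal(b$baseline_value, 95)
  o <- oracle_baseline(h$timestamp, h$creatinine_umol_l, T0)
  expect_equal(b$baseline_value, o$value)
  expect_equal(b$status, o$status)
})

test_that("window boundaries are pinned: 7-day edge, 48-hour edge, 365-day edge", {
  # a value exactly 7 days old is outside the open 7-day window and
  # becomes the fallback baseline
  edge7 <- make_measurements(-7 * 24, 80)
  b <- select_baseline(edge7, T0)
  expect_equal(b$status, "found_365d")
  expect_equal(b$baseline_value, 80)

  # exactly 48 h old is outside the delta window
  d <- evaluate_delta_48h(make_measurements(-48, 100), T0, 200)
  expect_false(d$delta_fired)
  expect_true(is.na(d$delta_value))

  # exactly 365 days old is still a valid fallback; just beyond is not
  expect_equal(select_baseline(make_measurements(-365 * 24, 90), T0)$status, "found_365d")
  expect_equal(select_baseline(make_measurements(-365 * 24 - 1, 90), T0)$status, "none")
})

test_that("delta criterion compares against the 48-hour minimum, inclusively", {
  # threshold equality fires
  d <- evaluate_delta_48h(make_measurements(-24, 100), T0, 126.5)
  expect_true(d$delta_fired)
  expect_equal(d$delta_value, 26.5)

  # prior value outside the window does not count
  d <- evaluate_delta_48h(make_measurements(-49, 100), T0, 200)
  expect_false(d$delta_fired)

  # the in-window minimum drives the delta, not the latest value
  d <- evaluate_delta_48h(make_measurements(c(-40, -10), c(120, 95)), T0, 130)
  expect_true(d$delta_fired)
  expect_equal(d$delta_value, 35)
})

test_that("ratio criterion is inclusive at 1.5 and accepts fallback baselines", {
  h7 <- make_measurements(-5 * 24, 80)
  b <- select_baseline(h7, T0)
  expect_true(evaluate_ratio(120, b)$ratio_fired) # exactly 1.5x
  r <- evaluate_ratio(119, b)
  expect_false(r$ratio_fired)
  expect_equal(r$ratio_value, 119 / 80)

  bfb <- select_baseline(make_measurements(c(-400, -200, -30) * 24, c(90, 85, 95)), T0)
  r <- evaluate_ratio(150, bfb)
  expect_true(r$ratio_fired)
  expect_equal(r$ratio_value, 150 / 95)

  none <- select_baseline(make_measurements(numeric(0), numeric(0)), T0)
  expect_error(evaluate_ratio(150, none), "none")
})

test_that("flowchart composes criteria, the 365-day rule and display policy", {
  demo <- make_demographics()
  idx <- make_measurements(0, 130)

  # both criteria evaluated independently; either one fires
  a <- evaluate_flowchart(make_measurements(-3 * 24, 80), idx, demo)
  expect_equal(a$outcome, "positive")
  expect_true(a$ratio_fired)
  expect_false(a$delta_fired) # 80 is outside the 48 h window
  expect_true(a$display)

  # no measurement in the prior 365 days: unable to compute, with the
  # explanatory memo
  a <- evaluate_flowchart(make_measurements(-400 * 24, 90), idx, demo)
  expect_equal(a$outcome, "unable_to_compute")
  expect_match(a$memo, "365 days")

  # a minor's alert is computed but never displayed
  demo17 <- make_demographics(birth_date = as.Date(T0) - round(17.5 * 365.25))
  a <- evaluate_flowchart(
    make_measurements(-24, 60), make_measurements(0, 120), demo17
  )
  expect_equal(a$outcome, "positive")
  expect_false(a$display)

  # dialysis department: displayed nowhere
  a <- evaluate_flowchart(
    make_measurements(-24, 60, department = "dialysis"),
    make_measurements(0, 120, department = "dialysis"), demo
  )
  expect_equal(a$outcome, "positive")
  expect_false(a$display)
})

test_that("missing demographics yield a warning and a never-displayed alert", {
  m <- make_measurements(c(-24, 0), c(60, 130))
  expect_warning(
    a <- detect_alerts(m, make_demographics(patient_id = "other")),
    "demographics"
  )
  expect_equal(a$outcome[2], "positive")
  expect_false(any(a$display))
})

test_that("non-positive creatinine is rejected up front", {
  m <- make_measurements(c(-24, 0), c(-5, 130))
  expect_error(detect_alerts(m, make_demographics()), "positive")
  expect_error(
    select_baseline(make_measurements(-24, 0), T0),
    "positive"
  )
})

test_that("memo text matches the outcome and negatives carry none", {
  expect_match(render_memo("positive"), "acute kidney injury \\(AKI\\)")
  expect_match(render_memo("positive"), "nephrotoxic medication")
  expect_match(render_memo("unable_to_compute"), "previous 365 days")
  expect_identical(render_memo("negative"), "")
  expect_error(render_memo("sideways"), "unknown")
})

test_that("equal-valued minima report the most recent timestamp", {
  h <- make_measurements(c(-6, -3, -2) * 24, c(70, 70, 90))
  b <- select_baseline(h, T0)
  expect_equal(b$baseline_value, 70)
  expect_equal(b$baseline_time, at_days(-3))
})

test_that("flowchart agrees with the brute-force oracle on random series", {
  set.seed(101)
  demo <- make_demographics()
  for (rep in 1:150) {
    s <- random_series(sample(2:25, 1))
    n <- nrow(s)
    idx <- s[n, , drop = FALSE]
    hist <- s[-n, , drop = FALSE]
    a <- evaluate_flowchart(hist, idx, demo)
    expected <- oracle_outcome(
      hist$timestamp, hist$creatinine_umol_l,
      idx$timestamp, idx$creatinine_umol_l
    )
    expect_equal(a$outcome, expected)
    ob <- oracle_baseline(hist$timestamp, hist$creatinine_umol_l, idx$timestamp)
    expect_equal(a$baseline_status, ob$status)
    if (ob$status != "none") expect_equal(a$baseline_value, ob$value)
  }
})

test_that("raising the index value never turns a positive alert negative", {
  set.seed(202)
  demo <- make_demographics()
  for (rep in 1:40) {
    s <- random_series(sample(3:15, 1))
    n <- nrow(s)
    hist <- s[-n, , drop = FALSE]
    idx <- s[n, , drop = FALSE]
    a1 <- evaluate_flowchart(hist, idx, demo)
    idx2 <- idx
    idx2$creatinine_umol_l <- idx$creatinine_umol_l + runif(1, 1, 150)
    a2 <- evaluate_flowchart(hist, idx2, demo)
    if (a1$outcome == "positive") expect_equal(a2$outcome, "positive")
  }
})

test_that("identical inputs produce identical alert records", {
  co <- small_cohort(n = 30L)
  a1 <- detect_alerts(co$measurements, co$demographics)
  a2 <- detect_alerts(co$measurements, co$demographics)
  expect_identical(a1, a2)
})

test_that("negative alerts are never displayed and carry no memo", {
  co <- small_cohort(n = 60L)
  a <- detect_alerts(co$measurements, co$demographics)
  neg <- a[a$outcome == "negative", ]
  expect_gt(nrow(neg), 0)
  expect_false(any(neg$display))
  expect_true(all(neg$memo == ""))
})
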
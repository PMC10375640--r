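Package: akialert
Title: KDIGO Creatinine E-Alert Engine for Acute Kidney Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine that evaluates plasma creatinine time series
    against KDIGO stage-1 criteria (an absolute rise of 26.5 umol/L within
    48 hours, or a 1.5-fold rise over a 7-day minimum baseline with a
    365-day most-recent fallback) and emits electronic alerts with
    display and phone-notification policies, episode segmentation,
    before-after awareness endpoints (2-day creatinine follow-up,
    7-day nephrotoxic medication discontinuation) compared with
    continuity-corrected chi-square tests, and a synthetic electronic
    health record cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
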
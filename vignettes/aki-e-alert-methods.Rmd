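---
title: "Methods: the AKI creatinine e-alert and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the AKI creatinine e-alert and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akialert)
```

## The problem

Acute kidney injury (AKI) is a sudden loss of kidney function, visible in
routine laboratory data as a rise in plasma creatinine (PCr), yet it is
chronically under-recognized on the ward. The KDIGO guidelines define
stage-1 AKI through two creatinine-change criteria, which lend themselves
to automation: every new creatinine result can be screened against the
patient's own recent history, and the requesting physician alerted when
the criteria fire. `akialert` implements such a rule engine together with
the surrounding machinery a hospital deployment needs — a notification
policy that limits alert fatigue, segmentation of alerts into AKI
episodes, and a before-after evaluation of whether the alert changed
physician behaviour — plus a synthetic EHR cohort generator so that every
stage is testable without patient data.

## The detection rule

For an index measurement with value $c_t$ (µmol/L) at time $t$, the engine
evaluates:

* **Absolute criterion**: $c_t - \min\{c_s : s \in (t-48\,\mathrm{h},\, t)\}
  \ge 26.5$ µmol/L.
* **Ratio criterion**: $c_t / b_t \ge 1.5$, where $b_t$ is the baseline.

The baseline $b_t$ is the *minimum* creatinine in the window
$(t-7\,\mathrm{d},\, t)$. When that window is empty, the *most recent*
value in $[t-365\,\mathrm{d},\, t-7\,\mathrm{d}]$ is used instead; when
that too is empty the outcome is "unable to compute" (surfaced with its
own explanatory memo, since a missing baseline is itself clinically
informative). An alert is **positive** when either criterion fires.
Stage-2/3 grading, urine output and eGFR are deliberately out of scope:
the engine grades nothing beyond the stage-1 trigger.

### Window and threshold conventions

Several conventions are under-determined by the clinical definitions; the
package fixes them as follows and pins each with a test:

* Look-back windows are half-open towards the index instant — a
  measurement can never serve as its own baseline. A value exactly 48 h
  old is outside the delta window; a value exactly 7 d old falls into the
  fallback window; a value exactly 365 d old is still a valid fallback.
* Threshold comparisons are inclusive (`>=`), matching the usual reading
  of the KDIGO stage-1 definitions.
* The absolute criterion compares against the minimum over the whole 48 h
  window (the most sensitive reading, consistent with the minimum-based
  baseline); the 365-day fallback feeds only the ratio criterion, since a
  value older than 7 days cannot witness a rise "within 48 h".
* Equal-valued minima report the most recent timestamp as the baseline
  time (the value is unaffected); simultaneous timestamps keep ingestion
  order.
* Age is evaluated at the index measurement's timestamp; adults are
  `age >= 18`.
* Timestamps are compared on a single UTC clock; zone offsets in input
  files are normalized at ingestion. "Now" never enters the engine — the
  index timestamp is the only clock, so replaying a stream is exactly
  reproducible.

## Notification policy

Positive and unable-to-compute outcomes are displayed in the EHR for
adult patients outside the dialysis department; negative outcomes are
never shown. Phoning is more restrictive, to keep the laboratory's
workload and the physicians' alert fatigue low: dialysis, ICU and
COVID-ward patients are never phoned (they are already under close
surveillance), and a positive alert is suppressed when a phoned alert
occurred within the previous 7 days — *unless* a non-triggering
measurement intervened. That reset rule is the one reading that
reproduces both deployed behaviours simultaneously: a string of positive
alerts in one week yields a single call, while positives on day 1 and
day 3 with a normal value on day 2 yield calls on both days (the day-2
result suggests recovery, so a new rise is new information). An
unable-to-compute result is treated as non-triggering for this purpose —
it does not assert ongoing AKI.

## Episodes and endpoints

Endpoint analysis on raw alerts would double-count patients whose
creatinine stays elevated, so alerts are segmented into episodes with a
window *anchored* at the first alert: positive alerts strictly within
7 days of the episode start join it; the first alert at or beyond 7 days
starts a new episode. Anchored (rather than rolling) windowing is pinned
by a dedicated test: alerts on days {0, 5, 9} form episodes {0, 5} and
{9}, where a rolling window would merge all three. The episode and
phone-suppression windows are separate parameters that both default to
7 days.

Two awareness endpoints are computed per episode, each anchored at the
first alert's measurement time (not the communication time, which the
data model does not carry):

* **Follow-up**: at least one creatinine measurement in
  $(t_0, t_0 + 48\,\mathrm{h}]$ — 48 hours rather than calendar days,
  consistent with the delta criterion's phrasing.
* **Medication stop**: among nephrotoxic medications (a configurable
  identifier list) active at $t_0$ (interval $[\mathrm{start},
  \mathrm{stop})$, missing stop = ongoing), at least one stop in
  $(t_0, t_0 + 7\,\mathrm{d}]$. Episodes without nephrotoxic exposure are
  excluded from this endpoint's denominator; dose reductions are out of
  scope.

Episodes of COVID-cohort patients and episodes starting in an ICU
department are excluded from the analysis population, with explicit
exclusion accounting.

Before-after comparisons build a 2×2 table (period × outcome) per
endpoint and stratum and test it with Pearson's chi-square *with Yates
continuity correction* — the variant that reproduces the printed
p-values of the pilot's published episode table from its printed counts;
the uncorrected test remains available behind `correct = FALSE`.
Degenerate tables (an empty period, a zero outcome margin) are flagged
and carry `NA` statistics rather than erroring, so a stratum present in
only one period degrades gracefully. Percentages print to one decimal;
p-values print to three decimals, `<0.001` below that and `1.0` at the
top, with the raw value always retained.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the study conditions of a
six-month before-after pilot at a tertiary hospital:

* **Scale**: 1000 patients per period with an 88% injected-event rate,
  yielding ≈ 850 analysable episodes per period after ~4% COVID/ICU
  exclusions — the scale of the pilot this design mirrors.
* **Baseline creatinine**: log-normal by sex, median 70 (female) /
  85 (male) µmol/L, sdlog 0.2. These are population-plausible stand-ins,
  configurable and never treated as empirical facts.
* **Sampling cadence**: ED/ICU ≈ 12 h, ward ≈ 1 d, outpatient ≈ 30 d.
  Outpatients therefore alert off the 365-day fallback baseline — which
  is how the generator produces a realistic mix of 7-day and fallback
  baselines (the deployed system saw roughly four fifths 7-day).
* **Events**: with probability `aki_event_rate` a patient's latent
  trajectory is multiplied by `fold_change` (default 2.0) at an anchor
  drawn uniformly in the period, held for a day, then decayed back over
  7 days. The excursion modifies the *latent* trajectory before
  multiplicative measurement noise (default sdlog 0.04, settable to 0) is
  sampled, so "detectable by construction" is well defined: an event is
  detectable when its fold change reaches 1.5, or its absolute rise
  reaches 26.5 µmol/L while the setting's cadence guarantees a
  measurement inside the 48 h window.
* **Endpoints**: follow-up measurements, nephrotoxic exposure and stop
  times are Bernoulli draws with per-period probabilities
  (0.57/0.66 follow-up, 0.592/0.632 exposure, 0.778/0.853 stop — the
  magnitude of the published pilot proportions), so effect sizes are
  known by construction and parameter recovery is testable. The
  follow-up probability is a per-period scalar, uniform across settings;
  setting-specific probabilities are configurable but not defaulted.
* **Determinism**: one master seed drives independent sub-streams per
  table (demographics + latent events, measurements, medications), so the
  same seed reproduces every table exactly and changing, say, medication
  parameters never perturbs the measurement table.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: assay analytics and reporting
artefacts beyond simple rounding, inter-current illness and seasonal or
pandemic confounding, transfers between departments mid-episode,
medication prescribed outside the hospital, pharmacokinetics of specific
nephrotoxins, and patients appearing in both periods. Its purpose is
mechanical soundness (detection, segmentation, counting, testing), not
epidemiological realism.

`truth_match()` links injected events to positive alerts within a 48 h
tolerance. Late re-alerts of a decaying episode (more than 48 h after the
event) are counted in its "false alert" tally by construction of that
window; on default settings they are a few per thousand measurements and
are genuine in-episode alerts, not detector errors.

## Numerical and degenerate-input choices

* All time arithmetic is in seconds on POSIXct/UTC; no floating-point
  window arithmetic beyond that.
* Non-positive or comparator-coded creatinine (`"<5"`), unparseable
  timestamps, unknown sex codes and stop-before-start medication rows are
  rejected at validation with row-level issue reports; exact duplicate
  rows are deduplicated with a warning. Missing required columns are
  fatal and name the column.
* Patients missing from demographics still get computed alerts (one
  warning), but those alerts are never displayed — the safe default for
  a display rule that depends on age.
* An empty analysis population, or period boundaries excluding all data,
  complete with a degenerate flagged report, not an error.

## Problem sizes used by the test suite

The suite checks the detector against an exhaustive brute-force
evaluator on 1,000 random series (2–30 measurements over 400 days);
recovers the configured endpoint probabilities within three binomial
standard errors on a full-scale cohort (~850 episodes per period); and
estimates the corrected test's null rejection rate from 600 simulated
2×2 tables at n = 850 per period, checking it stays within 5% ± 3
Monte-Carlo standard errors. These sizes keep the whole suite under a
minute on one CPU while leaving the binomial error bands tight enough to
be meaningful.

## Known limitations

* The engine grades only the stage-1 trigger; staging progression is not
  modelled.
* The 365-day fallback baseline can be stale; the deployed system
  accepted this trade-off, and the package reports the share of alerts
  that relied on it (`baseline_window_share()`) so users can monitor it.
* The before-after design inherits all its usual confounders (season,
  case mix, co-interventions); the package quantifies proportions and
  tests, it does not adjust for anything.
* Phone/communication latency is not modelled; endpoint windows anchor at
  the measurement time.
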
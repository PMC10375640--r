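# akialert

A KDIGO-derived creatinine e-alert engine for acute kidney injury (AKI),
with the notification policy, episode segmentation and before-after
awareness evaluation a hospital deployment needs — and a synthetic EHR
cohort generator so the whole pipeline is testable without patient data.

It is written for clinical chemists, nephrology/data-science teams and
methodologists who want to prototype, audit or re-evaluate an automated
AKI alert on longitudinal laboratory data.

## The rule at the core

For each new plasma creatinine value $c_t$ (µmol/L) of a patient, the
engine fires a stage-1 AKI alert when either

* $c_t - \min\{c_s : s \in (t-48\,\mathrm{h},\,t)\} \ge 26.5$ µmol/L
  (absolute rise within 48 h), or
* $c_t / b_t \ge 1.5$ (rise over baseline),

where the baseline $b_t$ is the minimum creatinine in the previous
7 days, falling back to the most recent value between 365 and 7 days ago,
and "unable to compute" when no value exists within 365 days. Around the
detector sit:

* a display/phone policy (adults only in the EHR, no display for
  dialysis; no calls to dialysis/ICU/COVID wards; a 7-day phone
  suppression window that a non-triggering measurement resets),
* episode segmentation anchored at the first positive alert (7-day
  window),
* two awareness endpoints per episode — a creatinine follow-up within
  48 h, and discontinuation of at least one active nephrotoxic drug
  within 7 days — compared between a *before* and an *after* period with
  Yates-corrected chi-square tests, stratified by department, specialty
  and sex.

See `vignettes/aki-e-alert-methods.Rmd` for the full account of the
conventions (window boundaries, tie-breaks, degenerate inputs) and of
what the simulator does and does not emulate.

## Worked example

Simulate a small two-period cohort and run the full pipeline:

```r
library(akialert)

cohort <- simulate_cohort(sim_config(
  n_patients = c(before = 300L, after = 300L), seed = 42L
))
result <- run_pipeline(
  cohort$measurements, cohort$demographics,
  cohort$medications, cohort$nephro_list
)
```

The stage log prints the deployment-style accounting:

```
detect: 3508 measurements from 600 patients
detect: 789 positive, 2119 negative, 600 unable-to-compute
notify: 525 alerts phoned, 1386 displayed
episodes: 536 episodes from 789 positive alerts
analysis population: 510 episodes retained, 26 excluded (covid_cohort: 15, icu_department: 11)
evaluation: 261 before / 249 after episodes (0 outside both periods)
```

and `print(result)` renders the before-after report (excerpt):

```
AKI e-alert before-after evaluation
7-day baselines among triggering alerts: 663 of 789 (84.0%)

PCr follow-up within 2 days
  overall            overall                147/261   (56.3%)  vs    154/249   (61.8%)   p = 0.239
  start_department   ED                      22/42    (52.4%)  vs     28/49    (57.1%)   p = 0.807
  ...

Nephrotoxic medication stop within 7 days
  overall            overall                128/164   (78.0%)  vs    129/150   (86.0%)   p = 0.093
  start_department   outpatient              26/37    (70.3%)  vs     34/36    (94.4%)   p = 0.017
  ...
```

Reading: each row is one 2×2 comparison — numerator/denominator and
percentage of episodes meeting the endpoint in the before vs after
period, with the continuity-corrected chi-square p-value. At 300
patients per period the simulated awareness effect (follow-up 0.57 →
0.66 by construction) is visible but not yet significant overall; at the
default pilot scale (1000/period) it is. The individual pieces are
exported too: `detect_alerts()`, `phone_decisions()`,
`segment_episodes()`, `filter_analysis_population()`,
`episode_outcomes()`, `compare_periods()`, `stratified_report()`,
`two_by_two()`, `truth_match()`.

A command-line surface wraps the same functions:

```sh
Rscript inst/cli/akialert.R simulate --out cohort/ --seed 12
Rscript inst/cli/akialert.R run-all --dir cohort/ --out results/
# or stage by stage: detect, episodes, evaluate
```

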
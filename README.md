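# careburden

Quantifying informal caregiver burden in long-term care (LTC), and
analyzing what drives it and what relieves it.

Taiwan's LTC intake assessment (the Case Management Evaluation Form,
300+ questions) does not administer any international caregiver-burden
instrument. `careburden` implements a **CSI-based burden score**: nine
intake items mapped onto Caregiver Strain Index concepts — two six-level
ordinals contributing 0–1 in 0.2 steps (how long the recipient can be left
alone; the caregiver's self-rated quality of life) and seven yes/no items
contributing 0/1 — summing to a score on the grid {0.0, 0.2, …, 9.0}.
Higher means more burdened.

Around the score, the package provides the full analysis pipeline for an
assessment cohort:

* **Cohort construction** — CONSORT-style exclusions (records that cannot
  be scored; under-18 caregivers or recipients), the post-2022 validation
  subset carrying the government Preliminary Screening Indicator (PSI),
  and the reassessed subset.
* **Validation** — score vs. two high-burden labels (PSI flags under a
  configurable k-of-10 rule; majority of three expert votes): AUROC,
  AUPRC (average precision), confusion metrics, Youden-index cut-point
  selection (BCP: the threshold maximizing sensitivity + specificity − 1),
  and Cohen's kappa between the labels with a Fleiss–Cohen–Everitt 95% CI.
* **Risk-factor screening** — one OLS model per assessment feature,
  `score ~ feature + 8 covariates` (recipient gender/age/disability
  certificate/dementia, foreign caregiver, CMS level, caregiver
  relationship and age), raw p-values with a Benjamini–Hochberg companion.
* **Survival analysis** — time from assessment to first use of each
  top-10 service within the assessment→reassessment window: Kaplan–Meier
  by burden group, log-rank, and Cox proportional hazards (Efron ties)
  with the continuous score as exposure, HR per unit score.
* **Service impact** — change-score regressions
  `Δscore ~ usage count + 8 covariates` per service with ≥ 30 unique users.
* **Synthetic cohort generator** — the study's raw data are restricted, so
  a calibrated generator reproduces the published cohort arithmetic
  (32,955 → 28,335 included; 1,791 / 7,471 subsets), score moments
  (mean 4.21, SD 1.71; validation subset 4.03), label structure
  (prevalences 25%/12%, kappa 0.402, AUROC 0.77/0.72) and injects the
  published effect sizes (screening betas, hazard ratios 1.065/1.116/1.114,
  Table-2 change-score slopes) as recoverable ground truth.

## Worked example

```r
library(careburden)

sim <- simulate_study(default_generator_config(seed = 1))
fr <- apply_consort_filters(sim$records)
print(fr)
#> CONSORT filter report
#>   assessed:                 32955
#>   excluded, missing score:  4437
#>   excluded, under 18:       183
#>   included:                 28335

inc <- score_records(fr$included)
sprintf("score mean %.2f, SD %.2f", mean(inc$score), sd(inc$score))
#> "score mean 4.20, SD 1.72"

val <- attach_labels(select_validation_subset(inc))
cohens_kappa(val$psi_label, val$expert_label)
#> Cohen's kappa = 0.357 (95% CI 0.309 to 0.406), n = 1791
auroc(val$score, val$expert_label)  # 0.774
auroc(val$score, val$psi_label)     # 0.709

rea <- select_reassessed_subset(inc)
cox_fit(build_time_to_first(rea, sim$events, "home_respite"))
#> Cox PH: HR per unit score = 1.144 (95% CI 1.107-1.183), p = 2.46e-15
#>   n = 7471, events = 1196
```

Reading the output: the simulated cohort reproduces the published CONSORT
counts exactly (they are designated subsets, not random outcomes), and the
scored cohort lands on the published moments (4.21/1.71) within one draw's
sampling error. On the 1,791-case validation subset the two high-burden
labels agree moderately (kappa ≈ 0.36–0.45 across seeds, published 0.402),
and the score discriminates the expert label better (AUROC ≈ 0.77) than
the stricter PSI label (≈ 0.72) — the score is built from caregiver
self-report, as is the expert judgment. The Cox fit says each additional
score point raises the hazard of first home-respite use by ~14% in this
draw (injected truth 11.4%, inside the fitted CI): more burdened
caregivers reach for respite sooner.

The full pipeline, with reports written to disk:

```r
d <- tempdir()
write_study(sim, d)
report <- run_pipeline(pipeline_config(
  assessments = file.path(d, "assessments.csv"),
  events = file.path(d, "events.csv"),
  out_dir = file.path(d, "out")))
```

or from the shell via the CLI script (installed under
`system.file("cli", "careburden", package = "careburden")`):

```sh
careburden simulate --seed 1 --out study/
careburden run --assessments study/assessments.csv \
               --events study/events.csv --out study/out/
```

Subcommands: `simulate`, `score`, `cohort`, `validate`, `screen`,
`survival`, `impact`, `run`. The assessments-table schema is shipped as
`inst/extdata/data_dictionary.csv` (readable via `data_dictionary()`).

## Methods

The methods vignette (`vignettes/caregiver-burden-methods.Rmd`) documents
the score rubric and its boundary conventions, the label and threshold
machinery, the regression and survival models, the synthetic-data model
with its calibration (`scripts/calibrate.R`) and its stated limitations,
and the numerical edge-case policies.
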
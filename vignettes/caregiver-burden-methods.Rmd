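---
title: "Methods: a CSI-based caregiver burden score and its LTC analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a CSI-based caregiver burden score and its LTC analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careburden)
```

## The problem

Long-term care (LTC) intake assessments in Taiwan (the Case Management
Evaluation Form, 300+ questions) do not administer any of the international
caregiver-burden instruments, yet quantifying the burden carried by the
informal (family) caregiver is what drives referral of high-risk caregivers
to support services. `careburden` implements a burden score assembled from
nine intake items that map onto Caregiver Strain Index (CSI) concepts, and
the downstream analyses that a burden score enables: validating it against
two independent high-burden labels, screening several hundred assessment
features for burden risk factors, relating burden to how quickly families
first adopt LTC services, and measuring whether sustained service use
changes burden by reassessment time.

The original study data are restricted (county-level administrative
records), so the package ships a calibrated synthetic cohort generator that
reproduces the published summary statistics and injects the published
effect sizes as recoverable ground truth. Every downstream analysis is
exercised, and graded, against that stated world.

## The score

Nine items contribute additively. Two are six-level ordinals mapped to
$\{0, 0.2, 0.4, 0.6, 0.8, 1.0\}$ — how long the care recipient can be left
alone (longer is easier), and the caregiver's self-rated quality of life
(better is easier) — and seven are yes/no items contributing $\{0, 1\}$:
physical strain, sleep disturbance, caring for other family members,
distress from the recipient's behavior, the recipient's emotional or
behavioral issues, work being affected, and feeling unable to cope. The
total therefore lives on the 46-point grid $\{0, 0.2, \dots, 9.0\}$; the
rubric is stored as a single auditable table constant (`score_rubric`).

Two boundary conventions matter. The alone-duration intervals are closed
on the left and open on the right ("6 h to less than 9 h"), and exactly
9 h falls in the top "over 9 h" category, so the six levels partition
$[0,\infty)$ plus "cannot be left alone". Records missing any of the nine
items are never partially scored: they are excluded by the cohort filter,
matching the published CONSORT flow (4,437 of 32,955 records), followed by
the under-18 exclusion (either party; 183 records), counted in that order.

## Labels and validation

Two high-burden labels validate the score on the post-2022 subset whose
records carry the government Preliminary Screening Indicator (PSI):

* **PSI label** — ten binary flags. The official positivity rule is not
  public, so the rule is configurable (`psi_label(indicators, k)`); the
  default flags a case when *any* indicator is positive, and that default
  is used everywhere downstream.
* **Expert label** — majority of three expert votes (at least two of
  three).

Discrimination is summarized by AUROC (rank/Mann–Whitney form with tie
correction) and AUPRC. AUPRC uses the right-continuous average-precision
estimator, not trapezoids: trapezoidal interpolation in PR space is
optimistically biased, so our AUPRC values can sit slightly below reports
that interpolate. Agreement between the two labels uses Cohen's kappa with
the large-sample Fleiss–Cohen–Everitt variance for its 95% CI (the source
report does not name its CI method; this is the standard choice, and it
reproduces the published interval on the published 2×2 margins).

The decision threshold ("best cut-off point", BCP) maximizes Youden's
$J = \text{sensitivity} + \text{specificity} - 1$ under the rule
*score > t ⇒ high burden*. Candidates are midpoints between consecutive
distinct observed scores — robust on a discrete grid — with ties broken
toward the lower threshold (favoring sensitivity). A subtlety worth
stating: at realistic prevalence and discrimination, $J(t)$ is very flat
for roughly a full score point around its maximum, so the *argmax* at
n ≈ 1,800 has a sampling SD of nearly half a point. The published cut-point
(4.4) should be read with that in mind, and so should ours.

## Risk-factor screening

One ordinary-least-squares model per candidate feature:

$$\text{score} \sim \text{feature} + \text{the eight fixed covariates},$$

the covariates being recipient gender, age, disability certificate,
dementia, foreign caregiver, CMS disability level, caregiver relationship
(dummy-coded, most frequent level as reference) and caregiver age.
Features enter raw (unstandardized), complete cases per model, classical
homoskedastic SEs. Raw $p < 0.05$ is the headline criterion, mirroring the
source convention of not correcting across the ~303 tests; a
Benjamini–Hochberg count is always reported alongside as an honesty
companion, never as a replacement. Covariate columns that are degenerate
on their own (constant, or aliased with other covariates) are dropped once
up front; any rank deficiency remaining in a feature's model then
implicates the feature itself, which is skipped and logged rather than
reported with a broken interpretation.

## Survival analysis

The observation window runs from initial assessment to reassessment
(typically 300–400 days); the event is the first utilization of a given
service inside the window, otherwise the case is censored at reassessment.
Events dated before the assessment are ignored with a log entry; events
after the reassessment leave the case censored; a first use on the
assessment day gets duration 0.5 days so durations stay positive.
Kaplan–Meier curves and log-rank tests compare the dichotomized groups
(score strictly above the BCP = high burden); the Cox proportional-hazards
model uses the *continuous* score as exposure with the same eight
covariates — both exposures are retained deliberately, as both appear in
the source analyses. Ties are handled with the Efron approximation
(day-resolution data make ties common; Efron is less biased than Breslow
at this tie density). Estimation is delegated to the `survival` package;
the test suite keeps independent oracles (hand product-limit arithmetic,
hand observed-minus-expected log-rank tables, grid-maximized partial
likelihood) so the delegation is continuously cross-checked. Monotone
likelihood (separation) warnings from the fitter are captured: fatal if
they concern the score exposure, otherwise attached to the result as
notes.

## Service-impact regression

On the reassessed subset, per service used by at least 30 unique cases:

$$\Delta\text{score} \sim \text{usage count} + \text{the eight covariates},$$

where $\Delta$ is reassessment minus initial score and the usage count is
the number of that service's utilization events inside the case's window
(the source is ambiguous between counts and sessions; counts are the
default aggregation).

## The synthetic cohort: what it states, and what it does not

A single scalar drives everything: a case's **raw burden** is linear in
its features and covariates plus Gaussian noise; the observed score is
that value rounded to the 0.2 grid and clamped to $[0, 9]$; the nine items
are a uniformly random decomposition of the grid score consistent with the
rubric; label latents and service hazards load on the (standardized)
observed score. Defaults state the published world:

* cohort arithmetic 32,955 → 4,437 + 183 excluded → 28,335 included;
  1,791 validation; 7,471 reassessed;
* score moments: overall mean 4.21, SD 1.71; the validation subset is
  generated ~0.19 raw points lower so its mean is the published 4.03 —
  this matters because the cut-point is selected on that subset;
* label model: expert prevalence 25%, PSI prevalence 12%, kappa 0.402,
  AUROC 0.77 (expert) and 0.72 (PSI), with a shared non-score latent
  component representing caregiver self-report signal seen by both
  instruments but not by the score;
* injected feature effects: the published top-ten betas (0.74 multi-care
  down to −0.07 independent bathing, plus three rare BPSD binaries at
  2.58–2.60 with 1–2% prevalence);
* service model: per-unit-score log hazard ratios ln(1.065), ln(1.116),
  ln(1.114) for accompanied outings, companion and home-respite services;
  first-use probabilities sized so unique-user counts match the published
  NoC; change-score slopes per Table 2 for five services, Gaussian change
  noise SD 0.8 (chosen so the published NoC give non-trivial power);
* windows Uniform(300, 400) days; fixed seed ⇒ byte-identical output.

Where the publication states no value, a single realistic choice was made
once and documented in the configuration (covariate distributions matching
an elderly LTC population, e.g. recipient age ~ N(76, 12²), caregiver age
~ N(58, 13²); feature prevalences between 3% and 60% for null features;
modest covariate effects on burden). These choices were not revisited
against test outcomes.

Two design decisions deviate from the most literal construction and are
worth their rationale:

1. **Score-first generation.** Rather than generating items from per-item
   cutpoints on a latent trait and letting the score emerge, the raw score
   is generated linearly and the items decompose it. This makes every
   injected regression coefficient an exact score-scale truth — per-item
   cutpoint models only recover coefficients after an uncontrolled
   attenuation — at the cost of item-level marginals being a modeling
   convenience rather than a claim about real item behavior.
2. **Capped-scale effect calibration.** The $[0,9]$ clamp attenuates
   large effects: a carrier of a rare BPSD feature pushed ~2.6 points up
   runs into the ceiling. Real scores are capped too, and the published
   coefficients were estimated on capped scores, so the injected *raw*
   slopes are calibrated (per feature) so that the capped-scale regression
   coefficient equals the published value.

The generator's free constants — intercept, noise SD, validation-subset
shift, two label loadings, two label thresholds, the shared label
component, and the per-feature raw slopes — are fixed by a one-shot
calibration routine (`calibrate_generator()`, n = 200,000, seed 0) whose
frozen output is the default configuration; `scripts/calibrate.R` records
the run. The per-vote and per-flag idiosyncratic noise scales (both 0.5)
are design constants the calibration conditions on; they were set where
the kappa target is reachable given the AUROC-pinned loadings.

**What a green test does not establish:** the generator assumes feature
independence given the latent burden, Gaussian noise, exponential
first-use times and a stationary window — none of which is claimed of the
real data. Parameter-recovery tests validate the *estimators* against the
stated world; they say nothing about unmeasured confounding, feature
dependence structure, or the PSI instrument's actual items, which are not
public.

## Numerical choices and degenerate inputs

* Scores are exact multiples of 0.2 internally (integer grid units / 5);
  grid membership is asserted to 1e-9.
* `confusion_at_threshold` with no positive predictions reports precision
  (and F1) as `NaN` with a warning — never a silent 0.
* `cohens_kappa` with both raters constant and agreeing returns kappa 1
  (chance agreement 1, observed 1); binary tables cannot produce chance
  agreement 1 without perfect agreement, so the rejection branch is
  unreachable there.
* `youden_threshold` needs at least two distinct scores and both classes;
  ties in J go to the lower threshold.
* OLS requires more observations than parameters; rank-deficient columns
  are dropped by QR pivoting and reported.
* Cox fitting: Efron ties, `survival::coxph` defaults for iteration; the
  score coefficient must be finite, separation in the exposure is fatal.
* Calibration bisection tolerances: 5e-4 on AUROC/kappa, 2e-4 on
  prevalences, 1e-4 on capped-scale effects.

## Scaling notes for the shipped tests

The type-I-error calibration of the screening stage uses 1,200 null
features on 400 records (binomial SE ≈ 0.6 percentage points) rather than
the 10,000 feature-replicates a dedicated simulation study would use; the
acceptance suite runs one full-size cohort (seed 1) plus eight replicate
validation draws for the label-model checks, because a single n = 1,791
draw cannot resolve bands like prevalence ±1.5 points (one draw's SE is
already ±1.0). The acceptance *script* averages the validation-subset
statistics over ten replicate draws for the same reason; cohort-level
quantities come from one full-size draw at the requested seed.

## Known limitations

* The PSI's real items and rule are not public; any-positive is a stated
  default, not a claim.
* The BCP is an argmax of a flat criterion; its sampling noise (~±0.45 at
  n = 1,791) dwarfs its grid resolution, in the real study as much as
  here.
* Change-score regression inherits the grid: a true change smaller than
  0.1 is invisible for an individual case and only recoverable in
  aggregate.
* No time-varying covariates, competing risks, frailty, or
  proportional-hazards testing beyond the fitter's own diagnostics; no
  imputation of missing score items (excluded, as published).
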
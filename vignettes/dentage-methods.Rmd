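---
title: "Dental age estimation with Willems-style score tables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental age estimation with Willems-style score tables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentage)
```

## The estimation problem

Forensic age estimation in children leans heavily on tooth development:
radiographic calcification of the permanent dentition is staged on
Demirjian's ordinal scale — `0` (crypt present, no calcification), then `A`
through `H`, where `H` means the apical root canal has closed and
development is complete. The Willems approach converts the stages of the
seven lower-left permanent mandibular teeth (FDI 31–37; the third molar is
excluded) directly into years: each combination of sex, tooth and stage
carries a score, and the estimated dental age is the sum

$$\widehat{A} \;=\; \sum_{t=31}^{37} s_{\text{sex}}(t, \text{stage}_t).$$

`dentage` implements this predictor, the weighted-ANOVA procedure that fits
population-specific score tables, and the validation toolkit used to decide
whether a population needs its own table: signed and absolute prediction
errors, RMSE with bootstrap intervals, paired Wilcoxon comparisons between
two tables, calibration slopes, and weighted kappa for observer agreement.
Because the radiograph datasets behind such studies are generally not
deposited, the package also ships a latent-maturation simulator that
generates staged cohorts with the statistical structure the analysis
assumes, so every stage of the workflow is testable end to end.

Throughout, prediction error is defined as
`error = chronological age − estimated age`; a *negative* error therefore
means the method *overestimates* age.

## The packaged Saudi Arabian table

The package includes a score table for Saudi Arabian children
(`willems_sa_table()`), transcribed from published sex-specific regression
coefficients covering stages B–H. The printed source rows required a
transcription rule: some rows carry fewer than seven values, with leading
dash glyphs. We right-align every row to the stage-H column — stage H is
attained by every tooth in the source's own stage-frequency table, so the H
cell cannot be empty — and read leading dashes as empty low-stage cells
(male tooth 31 then starts at stage C, female tooth 31 at stage D). The
reconstruction is internally consistent: summing the stage-H column gives
16.19 y for boys and 16.21 y for girls, and the all-D sums are 5.08 y and
5.54 y — mutually coherent ages that a column misalignment would destroy.
Two interior cells (stage C of tooth 36, both sexes) are genuinely empty in
the source and carry no entry. Cells absent from a table score 0; they are
the dummy-coded reference levels absorbed into the fit, so a sparse table is
still a complete predictor. Stage `0` is admitted as a scoreable stage with
contribution 0: the low-stage cells of the source table are empty precisely
because pre-A states contribute nothing beyond the reference.

## Fitting a population-specific table

`fit_coefficients()` regresses chronological age on per-tooth stage
indicator blocks by weighted least squares — the "weighted analysis of
variance" formulation used to build Willems-style tables. Conventions:

* **Reference levels.** Each tooth's lowest *observed* stage is its
  reference (coefficient 0), so sparse cohorts still fit.
* **Intercept folding.** The intercept is added to every tooth-31
  coefficient, including tooth 31's reference stage, so the fitted table
  predicts by a pure seven-term sum and `estimate_age()` reproduces the
  weighted-least-squares fitted values to numerical precision. This mirrors
  the large magnitude of the tooth-31 column in published tables: that
  column carries the baseline age.
* **Weighting.** The original method's weighting is not specified in the
  source literature, so two documented schemes are provided:
  `"uniform"` (ordinary least squares) and the default `"inv_var_ageband"`
  (two-pass: an OLS fit estimates residual variance per 1-year age band,
  and records are weighted by its inverse; bands too small to estimate a
  variance inherit the overall residual variance). The scheme used is
  recorded in the fit object.
* **Rank deficiency.** Stage levels that are perfectly confounded (e.g. a
  singleton stage level that coincides with another singleton) make the
  design rank deficient. By default this is an error naming the aliased
  levels; `on_alias = "drop"` instead removes the aliased columns with a
  warning and omits those levels from the table, which is what
  `run_pipeline()` uses, because realistic cohorts of a few hundred
  records routinely contain such collisions. A level without a coefficient
  falls back to score 0 at prediction time, with a warning for fitted
  tables.

`stratified_split()` reproduces the usual validation design: a random
partition stratified by sex crossed with 1-year age bands, each stratum
contributing `floor(n · fraction + 0.5)` records to the test set (round
half up), deterministic given a seed. The split fraction is a free
parameter (default 0.5), since published studies rarely state theirs.

## Validation statistics

`error_summary()` reports, per group (each sex and combined):

* **ME** — mean signed error, the direction of bias;
* **MAE** — mean absolute error, the magnitude;
* **RMSE** — root mean square error, which up-weights large errors; the
  identity `rmse² = me² + population variance` ties the three together and
  is enforced by tests to 1e−10.

The 95% confidence interval for the RMSE is a subject-level percentile
bootstrap (default 2000 resamples, seeded) — chosen because the source
literature never states its interval method, and the bootstrap is
assumption-free and reproducible.

`wilcoxon_signed_rank()` is implemented in-package so that the exact and
approximate branches are under test against sign-assignment enumeration:
zero differences are dropped (classic convention) and counted; for n ≤ 25
the null distribution of the positive-rank sum is computed exactly by
dynamic programming over doubled midranks (ties handled exactly); above
that a normal approximation with continuity and tie correction is used.

`compare_methods()` performs the paired two-table comparison: per-subject
errors under both tables, mean pairwise differences of signed and absolute
errors with their SDs, Wilcoxon p-values on the paired vectors, and
per-table RMSEs with bootstrap intervals. Swapping the tables negates every
signed difference.

`weighted_kappa()` implements chance-corrected ordinal agreement with
disagreement weights `|i−j|/(k−1)` (linear, the default) or its square
(quadratic); on a 2-level scale the quadratic version reduces to unweighted
Cohen's kappa. The weighting used is always recorded, since published
reliability figures rarely say which was applied. `calibration_slope()` is
the least-squares line of predicted on chronological age (slope 1,
intercept 0 = perfect calibration).

## The cohort simulator

`generate_cohort()` draws ages uniformly on the configured range (default
4–16 y) or to user-supplied per-band counts (the packaged
`willems_table1_age_bands()` mimics the source study's 1334-subject age
structure), assigns sex with probability `sex_ratio` (default 0.528,
matching 605 boys / 541 girls), and stages each tooth by a latent
maturation model: child `i` has a shared tempo deviation
`δ_i ~ N(0, σ_child)` and each tooth an independent timing deviation
`ε_it ~ N(0, σ_tooth)`; the observed stage is the highest `s` with mean
attainment age `μ(sex, t, s) ≤ age_i + δ_i + ε_it`, else `0`. Stages are
therefore ordinal and monotone in age by construction, with child-level
correlation across teeth — the structure the additive predictor assumes.

`default_params_like_study()` calibrates `μ` to the packaged reference
stage distribution (`willems_table2_distribution()`, stages A–H per sex and
tooth for children aged 4–16): for each cell, the model-implied marginal
attainment probability for uniform ages with Gaussian latent noise has the
closed form `E_a[Φ((a−μ)/σ)]`, which is inverted by root finding.
Cumulative targets are clamped to `[10⁻³, 1−10⁻³]` (several reference
columns are degenerate at low stages) and consecutive attainment ages are
kept strictly increasing with a minimum 0.01-y gap. The inversion is
deterministic, so calibration is exactly reproducible. The default noise
SDs `σ_child = σ_tooth = 0.5` y were chosen once as a plausible split of
maturation-tempo versus tooth-specific variability at the scale of
childhood dental development.

Two things the simulator deliberately does *not* emulate: missing teeth
(the eligibility filter's missing-tooth rule is exercised with explicitly
constructed records instead), and the full error magnitude of real
radiograph studies — with Gaussian latent noise at the default SDs, a
fitted table predicts simulated ages with an RMSE of roughly 0.6 y, whereas
real-cohort validations typically report RMSEs near 1.8 y, because real
staging carries observer error and biological variability beyond a shared
tempo. Passing tests on simulated cohorts therefore demonstrates
correctness of the estimators and workflow, not field performance.

`attach_additive_ages()` turns any staged cohort into a parameter-recovery
harness: it replaces chronological ages by the predictions of a known
coefficient table plus Gaussian noise, so the true generating model is
exactly that table; ages at or below 0.1 y are floored there and counted.
For recovery to be meaningful the truth table must be expressed in the
identifiable parameterization (per-tooth reference scores 0, baseline on
tooth 31), and every stage must be observed — the test harness uses
balanced designed stage vectors (reference share ≈ 0.26, the allocation
that minimizes the worst coefficient SE) rather than maturation-model
stages, which leave low stages unobserved at study-like ages. At 2000
records per sex with 0.25-y noise the worst coefficient SE is ≈ 0.02 y, so
the maximum error across all ~112 coefficients is typically 0.05–0.08 y;
the noise-free fit recovers the table to machine precision.

## The eligibility filter

`filter_eligible()` applies the three inclusion rules used in validation
studies of seven-tooth methods: age strictly below the bound (default 16 y
— a subject at exactly 16.0 is excluded), no missing stage among teeth
31–37, and not all seven teeth at stage H (a fully developed dentition
carries no age signal below the bound). Every exclusion reason is logged
per record; a record can trigger several. The bilateral
contralateral-tooth exclusion used when selecting radiographs cannot be
checked from a seven-tooth record and is out of scope.

## Problem sizes and numerical choices

The test suite runs the workflow at deliberately modest sizes: cohorts of
120–500 for pipeline and property tests, 2000 per sex for parameter
recovery, 10 000 for simulator calibration, 500 cohorts of 200 subjects
with 1000 bootstrap resamples for the RMSE-interval coverage check, and
2000 resamples elsewhere (the package default). Root finding in the
calibration uses tolerance 1e−9; rank decisions use `qr()`'s default
tolerance; exact Wilcoxon switches to the normal approximation above
n = 25 non-zero differences.

## Known limitations

* The packaged Saudi Arabian table is a transcription of printed
  coefficients, including the right-alignment reconstruction described
  above; it is not a refit, and the validation numbers printed alongside
  the source table are not reproducible without the original radiograph
  data.
* The conversion of Demirjian maturity scores (0–100) to age percentiles
  is not implemented; only direct score-table prediction is supported,
  with user-supplied tables accepted in the same file format.
* Negative or implausibly low estimates are returned as computed (with a
  warning), never clamped; clamping is a reporting decision, not an
  estimation one.
* Simulated cohorts understate real-world error magnitudes (see above), so
  absolute error levels from simulation should not be quoted as expected
  field performance.
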
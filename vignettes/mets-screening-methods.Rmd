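---
title: "Nonlaboratory screening for metabolic syndrome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlaboratory screening for metabolic syndrome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscreen)
```

## The problem

Metabolic syndrome (MetS) is a cluster of cardiometabolic abnormalities —
elevated blood pressure, abdominal obesity, dysglycemia, dyslipidemia — that
marks elevated cardiovascular risk. The 2009 harmonized definition (any three
of five criteria) is the accepted reference, but two of its five criteria
need blood chemistry (glucose, HDL-C, triglycerides), which is often
unavailable in low-income settings. `metscreen` implements the reference
definition alongside simplified screening rules built only from measurements
a community health worker can take (blood pressure, waist circumference) and
questionnaire items (personal and family cardiovascular history, diet,
smoking, alcohol), and quantifies what is lost by dropping the laboratory:
sensitivity, specificity, predictive values, chance-corrected agreement, and
the prevalence estimates each rule implies.

The package is organized the way the analysis runs: a cohort data model
(validation, derived measures, exclusions), a criteria engine, diagnostic
accuracy, prevalence estimation, prevalence-ratio regression, a synthetic
cohort generator, and a pipeline that ties them together. The generator is
first-class: it emulates the urban Haitian adult cohort whose aggregate
tables calibrate the package, so every stage runs and is tested without any
external data.

## The cohort data model

A cohort is a plain data frame, one row per participant, with up to three
repeated blood-pressure readings in wide columns. Three conventions matter:

* **Plausibility windows** (SBP 40–300 mmHg, DBP 30–200, waist 30–300 cm,
  HDL-C 0–200 mg/dL, triglycerides 0–1000, glucose strictly positive) are
  treated as *closed* intervals at both ends; the source ranges are given
  without open/closed notation, and the inclusive reading keeps a recorded
  value of exactly 1000 mg/dL triglycerides valid. Validation reports every
  out-of-window field; it never silently alters data.
* **Mean blood pressure** is the average of the *second and third* readings:
  the first reading is systematically inflated by an alerting reaction and
  is discarded. With only two readings the package averages both; with one
  it uses that reading; both fallbacks are flagged (`bp_fallback`) since the
  measurement protocol only describes the three-reading case.
* **Missingness** is a per-field `NA`; empty CSV cells map to it. A missing
  pregnancy flag is treated as *not pregnant* — exclusion requires an
  affirmative flag, so absent data cannot silently drop a record — whereas a
  missing criterion field *does* exclude, mirroring how the source analysis
  removed participants with incomplete MetS criteria.

## The criteria engine

Nine boolean criteria feed four definitions:

| Definition | Criteria | Score to meet |
|---|---|---|
| MetS-H | eBP, eWC, eGlu, low HDL-C, eTG | ≥ 3 of 5 |
| MetS-1 | eBP, eWC | 2 of 2 |
| MetS-2 | eBP, eWC, personal history, family history | ≥ 3 of 4 |
| MetS-3 | MetS-2 criteria + high fat intake + smoking/high alcohol | ≥ 4 of 6 |

Default cutoffs are the harmonized ones with the IDF sub-Saharan Africa
waist values: SBP ≥ 130 or DBP ≥ 85 mmHg or antihypertensive treatment;
waist ≥ 94 cm (men) / ≥ 80 cm (women); glucose ≥ 100 mg/dL fasting or
≥ 200 mg/dL nonfasting or treatment; HDL-C < 40 (men) / < 50 (women) mg/dL
or treatment; triglycerides ≥ 150 mg/dL or treatment. The source text and
its definitions table disagree on whether the BP/waist/TG cutoffs are
strict or inclusive; the package defaults to inclusive `≥` (the harmonized
convention) and makes every threshold's value *and* orientation
configurable (`default_thresholds()`, JSON round-trip), so the strict
reading is reproducible. Which orientation the original analysis used
cannot be determined from the published tables, and the package asserts
neither.

Two genuinely open points were resolved as follows. The prose description
of MetS-2 ("three or more of" a three-item list) is internally inconsistent;
the package follows the four-criterion, score-≥3 layout of the definitions
table, which is corroborated by the published criterion co-occurrence
(only 84% of MetS-2 positives have elevated waist — impossible if the
two MetS-1 criteria were required wholesale). And treatment flags are kept
separate per lipid criterion, with the CSV reader mapping a single
`on_lipid_treatment` column onto both, matching the one-drug-class wording
of the harmonized definition.

Missing inputs propagate through three-valued logic: an OR-criterion is
`TRUE` as soon as one input decides it (a single elevated reading, or a
treatment flag alone), `NA` while the unknown inputs could still change the
answer. At the definition level a participant is `positive` when the
criteria known true reach the score, `indeterminate` when the missing ones
could still reach it, `negative` otherwise. Indeterminate calls are
reported but excluded from 2×2 tables and prevalence denominators — the
same decision the source made by excluding incomplete records up front.

## Diagnostic accuracy and agreement

Each screening rule is cross-tabulated against MetS-H. Sensitivity,
specificity, PPV and NPV are binomial proportions; their 95% intervals are
exact Clopper–Pearson limits obtained from beta quantiles
(`qbeta(α/2, x, n−x+1)` and `qbeta(1−α/2, x+1, n−x)`), with the conventional
endpoints 0 and 1 at `x = 0` and `x = n`. The test suite checks this
construction against an independent numerical inversion of the binomial
tails and verifies ≥ 95% true coverage exhaustively for all `n ≤ 30`.

Cohen's kappa is `(p_o − p_e)/(1 − p_e)` with a Wald interval using the
Fleiss–Cohen–Everitt large-sample standard error. The source does not name
its kappa CI method; on the published MetS-1 cells this package computes
64.6 (61.1, 68.1), consistent with the printed 64.6 (61.0, 68.2), and the
printed interval is treated as a plausibility check rather than an exact
target. Agreement labels use the Landis–Koch bands (≤ 0 poor, to 0.20
slight, 0.40 fair, 0.60 moderate, 0.80 substantial, above almost perfect).
If both margins degenerate into a single cell, `p_e = 1` and kappa is
defined as 1 under perfect agreement and 0 otherwise, flagged `degenerate`.
Reports print kappa ×100 to one decimal; underlying CSVs keep full
precision, and presentation rounding is half-up.

## Prevalence

Crude prevalence carries a Clopper–Pearson interval. Stratified estimates
partition the calls, so stratum counts always pool back to the crude
counts. Direct age standardization uses the WHO 2000–2025 World Standard
Population, shipped as a five-year-band CSV and user-overridable. The
five-year weights are apportioned *uniformly by year of age* into the
analysis bands (18–29, 30–39, 40–49, 50–59, 60+, half-open edges), so the
18–29 band takes two fifths of the 15–19 weight, then renormalized over the
adult bands. The standardized point estimate is the convex combination
`Σ w_b p_b`; its variance `Σ w_b² p_b(1−p_b)/n_b` gives a
normal-approximation interval truncated to [0, 1]. The source does not say
how it collapsed the standard, whether it renormalized over 18+, or which
CI method it used for standardized rates; the choices above are this
package's own, and identity checks (standardizing with the cohort's own age
weights returns the crude rate exactly) pin down their correctness.

## Prevalence-ratio regression

The primary model is the log-binomial GLM: exponentiated coefficients are
prevalence ratios, the appropriate effect measure for a cross-sectional
outcome this common (an odds ratio would overstate it). Log-binomial
fitting is notoriously fragile because the log link does not respect the
`p ≤ 1` constraint, so the package starts the IRLS at the Poisson solution
(always finite) and accepts the fit only if it converges with all fitted
probabilities strictly inside the unit interval (below `1 − 1e−8`); glm's
internal step-halving handles the boundary approach. Otherwise the
robust-Poisson results are substituted with `convergence = "fallback_used"`
and a warning — the standard epidemiological fallback. Sensitivity
analyses: Poisson regression with HC0 sandwich standard errors
(`sandwich::vcovHC`) for prevalence ratios, and logistic regression for
odds ratios. All intervals are Wald on the log scale; no profile
likelihood. Covariates are categorical with declared reference levels (age
band under 30, male sex, secondary-or-higher education, income at or below
$1/day, current/former smoking — the last looks inverted but follows the
source's table layout literally). Unadjusted mode fits one covariate at a
time.

Closed-form identities anchor the tests: a saturated one-factor
log-binomial equals the ratio of stratum prevalences exactly, replicating
rows k times leaves estimates fixed and shrinks intervals by √k, and the
known-truth simulator recovers a female prevalence ratio of 2.5 at
n = 50,000 within three standard errors.

## The synthetic cohort generator

The generator emulates the enrollment data of an urban Haitian adult
cohort (58% female; age bands 28.7/18.9/17.5/16.9/17.9% from 18–29 through
60+). Only marginal tables and regression gradients were published, so the
dependence model is deliberately the simplest one that can hit both: a
Gaussian copula over the six continuous measures (SBP, DBP, waist, glucose,
HDL-C, triglycerides) with age- and sex-shifted marginals — normal on the
natural scale except lognormal glucose and triglycerides — and logistic
models on age and the latent scores for the binary fields (antihypertensive
and glucose treatment, personal and family history). Criterion booleans are
*never* written directly; they emerge from thresholding downstream, which
is what makes the generator a genuine test of the classification engine.
Three BP readings are drawn per participant with 4 mmHg within-person noise
and a +3 mmHg alerting bias on the first (discarded) reading. Nonfasting
participants (a configured 28.7% — the nonfasting subset size is not
published and is a free parameter) carry a small-probability postprandial
"spike" mixture so that about 3% exceed 200 mg/dL while the nonfasting
median barely moves, as the published medians require. Pregnancy (6% of
women under 45) and per-field missingness (1.4% per clinical field group)
are injected last, sized so that roughly 9% of generated records are
excluded — the published flow lost 284 of 3,005.

The correlation values and logistic coefficients are free calibration
parameters, documented in `synthetic_cohort_config()`, tuned once so that
at large n the generated cohort reproduces the published criterion
marginals (elevated BP 39.0%, elevated waist 44.9%, reduced HDL-C 40.6%,
elevated TG 13.5%, elevated fasting glucose 15.1% of the fasting subset),
the syndrome prevalences (MetS-H 21.2%, MetS-1/2/3 within 2 percentage
points), the female/male gradient (29.1% vs 10.4%), and the criterion
co-occurrence among MetS-H positives (elevated BP 82.9%, elevated waist
90.7%, reduced HDL-C 81.7%, within 5 percentage points). `calibration_report()`
recomputes this comparison for any generated cohort and flags gaps.

What the generator does *not* emulate: the true Haitian joint distribution
beyond the printed aggregates (no microdata exist to check it), household or
neighborhood clustering from the multistage sampling, digit preference and
other measurement artifacts, informative missingness (fields go missing at
random), and any longitudinal structure. Passing calibration therefore
shows that the pipeline recovers the aggregate structure it was pointed at —
not that it would reproduce person-level Haitian data.

One subtlety the test suite makes explicit: with the copula correlation
zeroed and all treatment/history flags off, the laboratory criteria are
independent *conditional on sex*, but not marginally, because the waist and
HDL-C thresholds are sex-specific — sex acts as a common cause of two
criteria even in an otherwise structure-free configuration. The
independence test conditions on sex for exactly this reason.

## Problem sizes and numerical choices

The test suite generates cohorts of 400–20,000 records and runs in well
under a minute; the calibration check uses n = 20,000 (Monte-Carlo error
about ±0.7 percentage points on a 40% marginal, comfortably inside the
2-point tolerance), and parameter recovery uses a single n = 50,000 fit
judged against 3 standard errors. Exact-interval coverage is enumerated
exhaustively for n ≤ 30 over a 1% grid of true proportions. Degenerate
inputs are handled explicitly rather than by exception where a defined
answer exists: zero-denominator metrics return `NA` with a reason,
empty-margin kappa is flagged, an empty readings list yields a missing mean
BP, and an empty cohort classifies to an empty table. Ties at thresholds
are governed entirely by the configured orientation; there is no hidden
epsilon in criterion evaluation.

## Known limitations

* The published cohort's person-level results (its regression table in
  particular) are not reproducible from aggregates; the package recovers
  its *printed* tables exactly and uses the regression gradients only to
  anchor the generator's effect sizes.
* The kappa interval is asymptotic; for very sparse 2×2 tables an exact or
  bootstrap interval would be preferable.
* The standardized-rate interval ignores the (zero) variance of the
  standard weights and uses a normal approximation; for very small strata a
  gamma-based interval would be more conservative.
* The log-binomial fallback changes the variance model (sandwich vs
  binomial); when `convergence` reports `fallback_used`, intervals are not
  strictly comparable with converged log-binomial fits.
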
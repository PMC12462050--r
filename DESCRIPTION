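Package: metscreen
Title: Nonlaboratory Screening Definitions for Metabolic Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies adults in cross-sectional cardiovascular cohort data
    under the 2009 harmonized (laboratory-based) metabolic syndrome definition
    and under simplified nonlaboratory screening definitions built from blood
    pressure, waist circumference, self-reported history and health behaviors.
    Quantifies the diagnostic accuracy of the simplified rules against the
    harmonized reference (sensitivity, specificity, predictive values with
    exact binomial confidence limits, Cohen's kappa), estimates crude,
    stratified and directly age-standardized prevalence against the WHO
    2000-2025 World Standard Population, and fits prevalence-ratio regressions
    (log-binomial, robust Poisson, logistic). Ships a calibrated synthetic
    cohort generator emulating an urban Haitian adult population so the whole
    pipeline runs and is tested without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
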
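Package: alsmet
Title: Metabolic and Nutritional Prognostic Analysis for Early ALS Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives resting-energy-expenditure and anthropometric indices
    from indirect calorimetry and bioimpedance measurements in amyotrophic
    lateral sclerosis (ALS) cohorts, computes the BMI-muscle-metabolism
    (BMM) prognostic index (BMI - 19.8) x (mREE/LSTM - 38), selects its
    cut-off by time-dependent ROC analysis, and runs the stratified
    survival workflow around it: Kaplan-Meier curves, log-rank tests and
    Cox proportional-hazards models (Efron ties), together with the
    Fisher-exact / Mann-Whitney / Spearman group-comparison machinery.
    Includes a seeded synthetic-cohort generator calibrated to published
    early-ALS summary statistics for end-to-end testing when patient-level
    data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
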
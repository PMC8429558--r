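# alsmet

Metabolic-nutritional prognostic analysis for early amyotrophic lateral
sclerosis (ALS) cohorts.

Hypermetabolism — resting energy expenditure out of proportion to lean
tissue — predicts poor prognosis in ALS, but its effect *reverses* with
nutritional state: harmful in normal-weight patients, apparently
protective in malnourished ones. The BMI-muscle-metabolism (**BMM**)
index couples the two axes into one signed product,

```
BMM = (BMI − 19.8) × (mREE/LSTM − 38)
```

where BMI is in kg/m², measured REE (mREE, kcal/day) comes from indirect
calorimetry via the abbreviated Weir equation
`1.44 (3.941 VO2 + 1.106 VCO2)`, and LSTM is lean soft tissue mass (kg)
from bioelectrical impedance. The pivots are clinical boundaries: BMI
19.8 is where percent ideal body weight (BMI/22) crosses the malnutrition
cut of 0.9, and 38 kcal/kg/day is the hypermetabolism cut on mREE/LSTM.
BMM ≥ 1 defines the high-risk group. The package is for neurologists and
biostatisticians who want to compute these indices on their own cohorts
and rerun the full stratified survival workflow around them.

What's inside:

* **Metabolic profiling** — `classify_profile()`: BMI, %IBW, ΔBMI,
  ΔALSFRS-R, RQ, Weir mREE, Harris–Benedict pREE, mREE/LSTM, mREE/pREE,
  the BMM index, and all classification flags with their exact boundary
  conventions.
* **Native survival machinery** — `km_estimate()`, `logrank_test()`,
  `cox_fit()` (Newton–Raphson, Efron ties, Wald inference), all
  cross-checked against independent oracles and the `survival` package in
  the test suite.
* **Group comparisons** — `fisher_exact_2x2()` (minimum-likelihood
  two-sided convention), `mann_whitney_u()` (exact for small untied
  samples), `spearman_rank()`, `median_iqr()`, `compare_groups()`.
* **Cut-off selection** — `td_roc()` (cumulative/dynamic time-dependent
  ROC with conditional Kaplan–Meier censoring weights), `roc_auc()`,
  `select_cutoff()` (Youden or preset).
* **Synthetic cohorts** — `synth_params()` / `generate_cohort()`: a
  seeded generator calibrated to published cohort summaries, with
  survival driven by the true BMM through a Weibull hazard; the test bed
  standing in for undeposited patient data.
* **Pipeline** — `run_study()` / `write_study()` orchestrate everything
  on any cohort CSV; `inst/cli/alsmet.R` is a thin command-line wrapper
  (`simulate` / `compute` / `analyze`).

## Worked example

```r
library(alsmet)

cohort <- generate_cohort(synth_params(n = 48, seed = 1))  # or read_cohort("cohort.csv")
head(classify_profile(cohort)[, c("bmi", "pct_ibw", "rq", "mree",
                                  "mree_per_lstm", "bmm")], 3)
#>     bmi pct_ibw   rq    mree mree_per_lstm    bmm
#> 1 19.68    0.89 0.63 1214.95         43.53  -0.65
#> 2 25.23    1.15 0.95 1109.83         33.83 -22.63
#> 3 20.56    0.93 0.79 1645.47         32.42  -4.22

result <- run_study(cohort)
result
```

Patient 1 is just under the malnutrition boundary (%IBW 0.89) *and*
hypermetabolic (43.5 ≥ 38), so the two factors nearly cancel and the BMM
index sits near zero; patient 2 is well-nourished with a low metabolic
rate, giving a strongly negative (low-risk) index. The study print-out
then shows the four-cell stratification, every log-rank stratification,
the ROC and the two adjusted Cox models:

```
ALS metabolic-nutritional study: 48 analysed (0 excluded)

Four-cell stratification (complete BMI and mREE/LSTM):
               metabolism
nutrition       hypermetabolic normometabolic
  malnourished              12              7
  normal_weight              9             18

Log-rank tests (survival from onset):
  hypermetabolic_all             chi2 =  0.035, p = 0.8515 (n = 46)
  hypermetabolic_normal_weight   chi2 =  3.030, p = 0.08176 (n = 27)
  hypermetabolic_malnourished    chi2 =  0.431, p = 0.5115 (n = 19)
  ...
Time-dependent ROC (km) at 24 months: AUC = 0.713 (10 cases, 31 controls)

Cox model, survival from onset:
               term     coef      se    hr ci_low ci_high      z       p
           high_bmm 1.176000 0.60330 3.242 0.9937  10.580 1.9500 0.05123
                age 0.073110 0.04451 1.076 0.9860   1.174 1.6430 0.10040
  ...
```

Read it the way the workflow intends: metabolism alone is not prognostic
overall (p = 0.85), the harmful signal concentrates in the normal-weight
stratum, and the high-BMM group carries an adjusted hazard ratio of about
3 at this 48-patient scale. `write_study(result, "out/")` exports the
augmented profile CSV, comparison tables (CSV/JSON), tidy KM curves, the
ROC curve and the Cox fits as JSON, plus a run log.

From a shell:

```sh
Rscript inst/cli/alsmet.R simulate --seed 1 --n 48 --out cohort.csv
Rscript inst/cli/alsmet.R analyze --in cohort.csv --out results/
```

## Documentation

The methods vignette (`vignettes/bmm-methods.Rmd`) documents the model
and every convention: boundary rules, tie handling, the Weir and
Harris–Benedict coefficient sets, the time-dependent ROC estimator, the
generator calibration and its known attenuation behaviour, and the
package's numerical tolerances.
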
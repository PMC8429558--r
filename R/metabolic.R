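#' @title Derived anthropometric and metabolic quantities
#' @description Vectorised building blocks for the metabolic profile: BMI,
#'   percent ideal body weight, monthly BMI and ALSFRS-R decline rates,
#'   respiratory quotient, measured REE (Weir), predicted REE
#'   (Harris-Benedict) and the BMM prognostic index.
#' @name metabolic-quantities
NULL

.check_positive <- function(x, name) {
  if (any(!is.na(x) & (!is.finite(x) | x <= 0)))
    stop(name, " must be positive", call. = FALSE)
  invisible(x)
}

#' Body mass index
#'
#' @param weight body weight in kg.
#' @param height height in metres.
#' @return BMI in kg/m2. `NA` inputs propagate.
#' @examples
#' compute_bmi(49.5, 1.5) # 22
#' @export
compute_bmi <- function(weight, height) {
  .check_positive(weight, "weight")
  .check_positive(height, "height")
  weight / height^2
}

#' Percent ideal body weight
#'
#' %IBW is the ratio of actual to ideal body weight, where ideal weight is
#' the weight giving a BMI equal to the ideal-BMI constant (default
#' 22 kg/m2). It therefore reduces to `bmi / ibw_bmi_constant` and is
#' returned as a fraction (0.9, not 90). Malnutrition is %IBW < 0.9,
#' i.e. BMI < 19.8 at the default constant.
#'
#' @param bmi BMI in kg/m2.
#' @param thresholds an [als_thresholds()] object.
#' @return %IBW as a fraction.
#' @export
percent_ibw <- function(bmi, thresholds = als_thresholds()) {
  .check_positive(bmi, "bmi")
  bmi / thresholds$ibw_bmi_constant
}

#' Monthly BMI change since onset
#'
#' `(admission BMI - premorbid BMI) / months since onset`; negative values
#' mean decline.
#'
#' @param premorbid_bmi,admission_bmi BMI in kg/m2.
#' @param months_since_onset months from symptom onset to admission (> 0).
#' @return signed kg/m2 per month.
#' @export
delta_bmi <- function(premorbid_bmi, admission_bmi, months_since_onset) {
  .check_positive(months_since_onset, "months_since_onset")
  (admission_bmi - premorbid_bmi) / months_since_onset
}

#' Monthly ALSFRS-R decline since onset
#'
#' `(48 - ALSFRS-R at admission) / months since onset`, the usual
#' progression-rate estimator anchored at the full score of 48.
#'
#' @param alsfrs_r ALSFRS-R total score, 0-48.
#' @param months_since_onset months from onset to admission (> 0).
#' @return non-negative points per month.
#' @export
delta_alsfrs <- function(alsfrs_r, months_since_onset) {
  if (any(!is.na(alsfrs_r) & (alsfrs_r < 0 | alsfrs_r > 48)))
    stop("alsfrs_r must be between 0 and 48", call. = FALSE)
  .check_positive(months_since_onset, "months_since_onset")
  (48 - alsfrs_r) / months_since_onset
}

#' Respiratory quotient
#'
#' VCO2/VO2 from indirect calorimetry; about 0.7 when oxidising fat and
#' 1.0 for carbohydrate.
#'
#' @param vo2 oxygen uptake, mL/min (> 0).
#' @param vco2 carbon-dioxide production, mL/min (>= 0).
#' @return the dimensionless ratio.
#' @export
respiratory_quotient <- function(vo2, vco2) {
  .check_positive(vo2, "vo2")
  if (any(!is.na(vco2) & vco2 < 0)) stop("vco2 must be non-negative", call. = FALSE)
  vco2 / vo2
}

#' Measured resting energy expenditure (abbreviated Weir equation)
#'
#' The Weir equation without urinary nitrogen,
#' `1.44 * (3.941 * VO2 + 1.106 * VCO2)`, with gas rates in mL/min,
#' giving kcal/day (1.44 converts kcal/min-scaled gas exchange to a day).
#'
#' @param vo2 oxygen uptake, mL/min.
#' @param vco2 carbon-dioxide production, mL/min.
#' @return mREE in kcal/day.
#' @examples
#' weir_mree(250, 200) # 1737.288
#' @export
weir_mree <- function(vo2, vco2) {
  if (any(!is.na(vo2) & vo2 < 0) || any(!is.na(vco2) & vco2 < 0))
    stop("gas volumes must be non-negative", call. = FALSE)
  1.44 * (3.941 * vo2 + 1.106 * vco2)
}

#' Predicted resting energy expenditure (Harris-Benedict)
#'
#' The original Harris-Benedict (1919) coefficient set:
#' men `66.4730 + 13.7516 W + 5.0033 H - 6.7550 A`,
#' women `655.0955 + 9.5634 W + 1.8496 H - 4.6756 A`,
#' with weight W in kg, height H in **cm**, age A in years.
#'
#' @param sex `"M"`/`"male"` or `"F"`/`"female"` (case-insensitive).
#' @param weight kg. @param height cm. @param age years.
#' @return pREE in kcal/day.
#' @examples
#' harris_benedict_pree("M", 70, 170, 60) # 1474.346
#' @export
harris_benedict_pree <- function(sex, weight, height, age) {
  .check_positive(weight, "weight")
  .check_positive(height, "height")
  .check_positive(age, "age")
  s <- toupper(substr(as.character(sex), 1L, 1L))
  if (any(!is.na(s) & !s %in% c("M", "F")))
    stop("sex must be male ('M') or female ('F')", call. = FALSE)
  male <- 66.4730 + 13.7516 * weight + 5.0033 * height - 6.7550 * age
  female <- 655.0955 + 9.5634 * weight + 1.8496 * height - 4.6756 * age
  ifelse(s == "M", male, female)
}

#' BMI-muscle-metabolism (BMM) index
#'
#' `(BMI - 19.8) * (mREE/LSTM - 38)` at the default thresholds. The first
#' factor changes sign at the malnutrition boundary (BMI 19.8 = 0.9 x 22)
#' and the second at the hypermetabolism boundary (38 kcal/kg/day), so the
#' index is large and positive both for hypermetabolic normal-weight
#' patients and for normometabolic malnourished patients -- the two
#' configurations with poor prognosis -- and the metabolism effect
#' reverses sign across nutritional strata.
#'
#' @param bmi BMI in kg/m2.
#' @param mree_per_lstm mREE/LSTM in kcal/kg/day.
#' @param thresholds an [als_thresholds()] object.
#' @return the signed index; `NA` if either factor is missing.
#' @examples
#' bmm_index(22.0, 40.6) # 2.2 * 2.6 = 5.72
#' bmm_index(18.0, 34.5) # (-1.8) * (-3.5) = 6.3: malnourished, normometabolic
#' @export
bmm_index <- function(bmi, mree_per_lstm, thresholds = als_thresholds()) {
  .check_positive(bmi, "bmi")
  .check_positive(mree_per_lstm, "mree_per_lstm")
  (bmi - thresholds$bmm_bmi_reference) *
    (mree_per_lstm - thresholds$hypermetabolism_cut)
}

# Required columns of a raw cohort table (one row per patient).
.record_columns <- c(
  "patient_id", "age", "sex", "height", "premorbid_weight",
  "admission_weight", "months_since_onset", "months_since_first_visit",
  "alsfrs_r", "bulbar_onset", "vo2", "vco2", "lstm", "body_fat_pct",
  "smi", "fbs", "ldl", "pef_pct", "vc_pct", "peg", "nppv",
  "followup_months_from_onset", "event")

#' Derive the full metabolic profile of a cohort
#'
#' Takes a raw patient table (see [read_cohort()] for the schema) and
#' appends every derived quantity and classification flag: BMI (admission
#' and premorbid), %IBW, monthly BMI and ALSFRS-R decline, RQ, mREE
#' (Weir), pREE (Harris-Benedict), mREE/LSTM, mREE/pREE, the BMM index,
#' and the flags `malnourished` (%IBW < 0.9, open bound),
#' `hypermetabolic` (mREE/LSTM >= 38, closed bound), `high_bmm`
#' (BMM >= 1), `excess_weight_loss` (loss strictly greater than 10% of
#' premorbid weight), `high_fat` (> 25% men / > 30% women), `low_rq`
#' (RQ < 0.85), `high_ldl` (LDL >= 100) and `high_mree_pree` (> 1.1).
#'
#' Any derived value or flag is `NA` exactly when one of its inputs is
#' missing; no row is dropped. The function is deterministic and
#' idempotent: rerunning it on its own output recomputes identical
#' columns.
#'
#' @param records data frame of raw patient records.
#' @param thresholds an [als_thresholds()] object.
#' @return the input data frame with the profile columns appended.
#' @export
classify_profile <- function(records, thresholds = als_thresholds()) {
  missing_cols <- setdiff(.record_columns, names(records))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  r <- records
  th <- thresholds

  r$bmi <- compute_bmi(r$admission_weight, r$height)
  r$premorbid_bmi <- compute_bmi(r$premorbid_weight, r$height)
  r$pct_ibw <- percent_ibw(r$bmi, th)
  r$delta_bmi <- delta_bmi(r$premorbid_bmi, r$bmi, r$months_since_onset)
  r$delta_alsfrs <- delta_alsfrs(r$alsfrs_r, r$months_since_onset)
  r$rq <- respiratory_quotient(r$vo2, r$vco2)
  r$mree <- weir_mree(r$vo2, r$vco2)
  r$pree <- harris_benedict_pree(r$sex, r$admission_weight,
                                 r$height * 100, r$age)
  r$mree_per_lstm <- r$mree / r$lstm
  r$mree_per_pree <- r$mree / r$pree
  r$bmm <- bmm_index(r$bmi, r$mree_per_lstm, th)

  r$malnourished <- r$pct_ibw < th$malnutrition_pct_ibw
  r$hypermetabolic <- r$mree_per_lstm >= th$hypermetabolism_cut
  r$high_bmm <- r$bmm >= th$bmm_cut
  r$excess_weight_loss <-
    (r$premorbid_weight - r$admission_weight) / r$premorbid_weight >
    th$weight_loss_cut
  fat_cut <- ifelse(toupper(substr(as.character(r$sex), 1, 1)) == "M",
                    th$fat_cut_male, th$fat_cut_female)
  r$high_fat <- r$body_fat_pct > fat_cut
  r$low_rq <- r$rq < th$rq_cut
  r$high_ldl <- r$ldl >= th$ldl_cut
  r$high_mree_pree <- r$mree_per_pree > th$mree_pree_cut
  r
}

# Profile columns appended by classify_profile(), in output order.
.profile_columns <- c(
  "bmi", "premorbid_bmi", "pct_ibw", "delta_bmi", "delta_alsfrs", "rq",
  "mree", "pree", "mree_per_lstm", "mree_per_pree", "bmm",
  "malnourished", "hypermetabolic", "high_bmm", "excess_weight_loss",
  "high_fat", "low_rq", "high_ldl", "high_mree_pree")
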
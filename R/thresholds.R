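#' Classification thresholds for metabolic-nutritional profiling
#'
#' Bundles every cut-point used to turn derived metabolic quantities into
#' the binary flags of [classify_profile()] and downstream stratified
#' analyses. Defaults are the definitions used for early-ALS prognostic
#' profiling: hypermetabolism as mREE/LSTM >= 38 kcal/kg/day, malnutrition
#' as %IBW < 0.9 (equivalently BMI < 19.8 kg/m2 at the ideal-BMI constant
#' of 22), a BMM-index cut of 1, mREE/pREE > 1.1, RQ < 0.85 (fat-dominant
#' fuel use), LDL >= 100 mg/dL, body fat above 25% (men) / 30% (women),
#' and excess weight loss as more than 10% of premorbid weight.
#'
#' @param hypermetabolism_cut mREE/LSTM cut, kcal/kg/day (flag closed: `>=`).
#' @param malnutrition_pct_ibw %IBW cut as a fraction (flag open: `<`).
#' @param bmm_cut BMM-index cut (flag closed: `>=`).
#' @param mree_pree_cut mREE/pREE cut (flag strict: `>`).
#' @param rq_cut respiratory-quotient cut (flag: `<`).
#' @param ldl_cut LDL cut, mg/dL (flag closed: `>=`).
#' @param fat_cut_male,fat_cut_female body-fat cuts, percent (flag strict: `>`).
#' @param weight_loss_cut excess-weight-loss fraction (flag strict: `>`).
#' @param ibw_bmi_constant ideal-body-weight BMI constant, kg/m2.
#' @param bmm_bmi_reference BMI reference subtracted in the BMM index, kg/m2.
#'   At the defaults this equals `malnutrition_pct_ibw * ibw_bmi_constant`
#'   (0.9 x 22 = 19.8); a warning is issued if a custom set breaks that
#'   identity, since the BMM index is built on it.
#' @param roc_horizon prognostic horizon for time-dependent ROC, months.
#'
#' @return An object of class `"als_thresholds"`: a named list of the values
#'   above.
#' @examples
#' th <- als_thresholds()
#' th$malnutrition_pct_ibw * th$ibw_bmi_constant  # 19.8, the BMI equivalent
#' @export
als_thresholds <- function(hypermetabolism_cut = 38,
                           malnutrition_pct_ibw = 0.9,
                           bmm_cut = 1,
                           mree_pree_cut = 1.1,
                           rq_cut = 0.85,
                           ldl_cut = 100,
                           fat_cut_male = 25,
                           fat_cut_female = 30,
                           weight_loss_cut = 0.10,
                           ibw_bmi_constant = 22,
                           bmm_bmi_reference = malnutrition_pct_ibw * ibw_bmi_constant,
                           roc_horizon = 24) {
  th <- list(
    hypermetabolism_cut = hypermetabolism_cut,
    malnutrition_pct_ibw = malnutrition_pct_ibw,
    bmm_cut = bmm_cut,
    mree_pree_cut = mree_pree_cut,
    rq_cut = rq_cut,
    ldl_cut = ldl_cut,
    fat_cut_male = fat_cut_male,
    fat_cut_female = fat_cut_female,
    weight_loss_cut = weight_loss_cut,
    ibw_bmi_constant = ibw_bmi_constant,
    bmm_bmi_reference = bmm_bmi_reference,
    roc_horizon = roc_horizon
  )
  bad <- vapply(th, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v <= 0, logical(1))
  if (any(bad))
    stop("thresholds must be single positive finite numbers; offending: ",
         paste(names(th)[bad], collapse = ", "))
  if (abs(th$bmm_bmi_reference -
          th$malnutrition_pct_ibw * th$ibw_bmi_constant) > 1e-8)
    warning("bmm_bmi_reference differs from malnutrition_pct_ibw * ",
            "ibw_bmi_constant; the BMM index no longer pivots at the ",
            "malnutrition boundary")
  structure(th, class = "als_thresholds")
}

#' Read thresholds from a JSON configuration file
#'
#' The file holds a single JSON object whose keys are any subset of the
#' [als_thresholds()] arguments; unspecified keys keep their defaults.
#'
#' @param path path to a JSON file.
#' @return An `"als_thresholds"` object.
#' @export
read_thresholds <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(als_thresholds))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown threshold fields in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(als_thresholds, cfg)
}

#' @export
print.als_thresholds <- function(x, ...) {
  cat("ALS metabolic-nutritional thresholds\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}
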
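#' Read a cohort CSV
#'
#' One header row; columns are the raw patient-record fields:
#' `patient_id, age, sex, height, premorbid_weight, admission_weight,
#' months_since_onset, months_since_first_visit, alsfrs_r, bulbar_onset,
#' vo2, vco2, lstm, body_fat_pct, smi, fbs, ldl, pef_pct, vc_pct, peg,
#' nppv, followup_months_from_onset, event`. Units: height in metres,
#' weights in kg, gas rates in mL/min, LSTM in kg, body fat / %PEF / %VC
#' in percent points, FBS and LDL in mg/dL, all times in months. `sex` is
#' `M`/`F`, booleans are `0`/`1`, missing values are empty cells.
#'
#' @param path CSV path.
#' @param validate run [validate_cohort()] on the result (default `TRUE`).
#' @return a data frame of patient records.
#' @export
read_cohort <- function(path, validate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  for (col in c("bulbar_onset", "peg", "nppv", "event"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  if (validate) validate_cohort(df)
  df
}

#' Write a cohort (or augmented profile) CSV
#'
#' Inverse of [read_cohort()]: booleans become `0`/`1`, missing values
#' empty cells. Profile columns appended by [classify_profile()] are
#' written as-is after the raw columns.
#'
#' @param records data frame of records or profiles.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  out <- records
  for (col in names(out))
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a raw cohort table
#'
#' Checks the schema (required columns present) and the row-level
#' invariants: positive height/weights, ALSFRS-R within 0-48, positive
#' VO2 where calorimetry is present, strictly positive onset-to-admission
#' time, and follow-up at least as long as onset-to-admission time.
#'
#' @param records data frame of raw patient records.
#' @return `records`, invisibly, if valid; otherwise an error whose
#'   message lists the offending rows and columns.
#' @export
validate_cohort <- function(records) {
  missing_cols <- setdiff(.record_columns, names(records))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- character(0)
  flag <- function(cond, what) {
    idx <- which(!is.na(cond) & cond)
    if (length(idx))
      bad <<- c(bad, sprintf("%s (rows %s)", what,
                             paste(utils::head(idx, 10), collapse = ",")))
  }
  flag(records$height <= 0, "height <= 0")
  flag(records$admission_weight <= 0, "admission_weight <= 0")
  flag(records$premorbid_weight <= 0, "premorbid_weight <= 0")
  flag(records$months_since_onset <= 0, "months_since_onset <= 0")
  flag(records$alsfrs_r < 0 | records$alsfrs_r > 48, "alsfrs_r outside 0-48")
  flag(records$vo2 <= 0, "vo2 <= 0")
  flag(records$followup_months_from_onset < records$months_since_onset,
       "followup shorter than onset-to-admission time")
  flag(!records$sex %in% c("M", "F") & !is.na(records$sex),
       "sex not in {M, F}")
  if (length(bad))
    stop("cohort validation failed: ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(records)
}
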
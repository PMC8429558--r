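#' Study configuration
#'
#' @param thresholds an [als_thresholds()] object.
#' @param roc_criterion cutoff-selection rule for the BMM time-dependent
#'   ROC: `"youden"` or `"preset"` (preset uses `thresholds$bmm_cut`).
#' @param cox_covariates profile columns entering the Cox models; the
#'   default is the adjusted model of the source analysis: high BMM group,
#'   age, ALSFRS-R, excess weight loss, bulbar onset and %VC.
#' @param origins survival origins to analyse (`"onset"`, `"admission"`).
#' @param min_age exclusion threshold; patients younger are excluded.
#' @return object of class `"study_config"`.
#' @export
study_config <- function(thresholds = als_thresholds(),
                         roc_criterion = c("youden", "preset"),
                         cox_covariates = c("high_bmm", "age", "alsfrs_r",
                                            "excess_weight_loss",
                                            "bulbar_onset", "vc_pct"),
                         origins = c("onset", "admission"),
                         min_age = 49) {
  roc_criterion <- match.arg(roc_criterion)
  origins <- match.arg(origins, several.ok = TRUE)
  structure(list(thresholds = thresholds, roc_criterion = roc_criterion,
                 cox_covariates = cox_covariates, origins = origins,
                 min_age = min_age),
            class = "study_config")
}

#' Apply the cohort exclusion rules
#'
#' Removes patients younger than `min_age` (strictly: `min_age` itself is
#' kept) and, when the optional columns `prior_ventilation` / `prior_peg`
#' are present, patients ventilated (including NPPV) or fed by PEG before
#' the index admission. Returns both the kept records and an exclusion
#' ledger with one reason per excluded patient.
#'
#' @param records raw cohort data frame.
#' @param min_age exclusion age (default 49).
#' @return list with `kept` (data frame) and `excluded` (data frame:
#'   `patient_id`, `reason`; empty when nothing is excluded).
#' @export
exclusion_filter <- function(records, min_age = 49) {
  reason <- rep(NA_character_, nrow(records))
  mark <- function(cond, why) {
    idx <- !is.na(cond) & cond & is.na(reason)
    reason[idx] <<- why
  }
  mark(records$age < min_age, sprintf("age < %g", min_age))
  if ("prior_ventilation" %in% names(records))
    mark(as.logical(records$prior_ventilation),
         "mechanical ventilation (incl. NPPV) before admission")
  if ("prior_peg" %in% names(records))
    mark(as.logical(records$prior_peg), "PEG before admission")
  out <- !is.na(reason)
  list(kept = records[!out, , drop = FALSE],
       excluded = data.frame(patient_id = records$patient_id[out],
                             reason = reason[out],
                             stringsAsFactors = FALSE))
}

# FNV-1a hash of a string, as 8 hex digits; used to fingerprint configs.
# Arithmetic kept inside double precision: xor on the low 24 bits only
# (code points fit there) and the multiply by the FNV prime 16777619 =
# 2^24 + 403 split so no intermediate exceeds 2^53.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 16777216
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- ((h %% 256) * 16777216 + h * 403) %% 2^32
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

# variables compared between metabolic groups within each nutritional
# stratum (the Table-1-style layout)
.table1_vars <- c("age", "female", "premorbid_bmi", "bmi", "delta_bmi",
                  "excess_weight_loss", "months_since_onset",
                  "months_since_first_visit", "alsfrs_r", "delta_alsfrs",
                  "bulbar_onset", "fbs", "ldl", "pef_pct", "vc_pct",
                  "body_fat_pct", "lstm", "mree_per_lstm", "mree_per_pree",
                  "low_rq", "smi", "peg", "nppv")
# variables compared between BMM-index groups (the Table-2-style layout)
.table2_vars <- c("age", "female", "bmi", "delta_bmi", "excess_weight_loss",
                  "months_since_onset", "alsfrs_r", "delta_alsfrs",
                  "bulbar_onset", "ldl", "vc_pct", "mree_per_pree",
                  "low_rq", "high_fat", "lstm", "smi", "peg", "nppv",
                  "event")
# Kaplan-Meier / log-rank stratifications (onset origin)
.km_strata <- list(
  hypermetabolic_all = list(flag = "hypermetabolic", subset = NULL),
  hypermetabolic_normal_weight = list(flag = "hypermetabolic",
                                      subset = quote(!malnourished)),
  hypermetabolic_malnourished = list(flag = "hypermetabolic",
                                     subset = quote(malnourished)),
  high_mree_pree = list(flag = "high_mree_pree", subset = NULL),
  excess_weight_loss = list(flag = "excess_weight_loss", subset = NULL),
  high_fat = list(flag = "high_fat", subset = NULL),
  high_ldl = list(flag = "high_ldl", subset = NULL),
  high_bmm = list(flag = "high_bmm", subset = NULL))

#' Run the full metabolic-nutritional prognostic study
#'
#' Orchestrates, in order: cohort validation and exclusion, profile
#' derivation ([classify_profile()]), the four-cell
#' nutrition-by-metabolism stratification, the two characteristic
#' comparison tables (metabolic groups within each nutritional stratum;
#' BMM-index groups), the Kaplan-Meier / log-rank suite over the standard
#' stratifications (metabolism overall and within each nutritional
#' stratum, mREE/pREE, excess weight loss, body fat, LDL, BMM group;
#' onset origin), the BMM time-dependent ROC at the configured horizon
#' with cutoff selection, and the adjusted Cox models for each configured
#' survival origin (listwise deletion within each model). Comparisons use
#' pairwise deletion per variable. A stratification with fewer than two
#' observed groups, or an undefined ROC/Cox input, is skipped with a
#' warning and recorded in `skipped` rather than aborting the run.
#'
#' @param cohort raw cohort data frame (e.g. from [read_cohort()] or
#'   [generate_cohort()]).
#' @param config a [study_config()] object.
#' @return object of class `"study_result"`: list with `profiles`,
#'   `excluded`, `four_cell`, `comparisons`, `km` (per stratification:
#'   `curves`, `logrank`), `roc`, `cutoff`, `cox` (per origin), `skipped`
#'   and `meta` (config echo, config hash, package version, n).
#' @export
run_study <- function(cohort, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  validate_cohort(cohort)
  excl <- exclusion_filter(cohort, config$min_age)
  prof <- classify_profile(excl$kept, config$thresholds)
  prof$female <- toupper(substr(as.character(prof$sex), 1, 1)) == "F"
  skipped <- character(0)
  note_skip <- function(what, why) {
    warning(what, " skipped: ", why, call. = FALSE)
    skipped <<- c(skipped, stats::setNames(why, what))
  }

  complete4 <- !is.na(prof$malnourished) & !is.na(prof$hypermetabolic)
  four_cell <- table(
    nutrition = ifelse(prof$malnourished[complete4], "malnourished",
                       "normal_weight"),
    metabolism = ifelse(prof$hypermetabolic[complete4], "hypermetabolic",
                        "normometabolic"))

  comparisons <- list()
  cmp <- function(data, group, vars, label) {
    vars <- setdiff(vars, group)
    g <- data[[group]]
    if (length(unique(g[!is.na(g)])) == 2L)
      comparisons[[label]] <<- compare_groups(data, group, vars)
    else note_skip(paste0("comparison '", label, "'"),
                   "grouping variable lacks two observed levels")
  }
  cmp(prof[!is.na(prof$malnourished) & !prof$malnourished, , drop = FALSE],
      "hypermetabolic", .table1_vars, "metabolism_normal_weight")
  cmp(prof[!is.na(prof$malnourished) & prof$malnourished, , drop = FALSE],
      "hypermetabolic", .table1_vars, "metabolism_malnourished")
  cmp(prof, "high_bmm", .table2_vars, "bmm_group")

  surv_onset <- survival_from(prof, "onset")
  km <- list()
  for (nm in names(.km_strata)) {
    st <- .km_strata[[nm]]
    rows <- if (is.null(st$subset)) rep(TRUE, nrow(prof))
            else !is.na(eval(st$subset, prof)) & eval(st$subset, prof)
    flag <- prof[[st$flag]]
    use <- rows & !is.na(flag) & !is.na(surv_onset$time) &
      !is.na(surv_onset$event)
    g <- flag[use]
    if (length(unique(g)) < 2L) {
      note_skip(paste0("KM stratification '", nm, "'"),
                "fewer than two observed groups")
      next
    }
    tt <- surv_onset$time[use]; ee <- surv_onset$event[use]
    curves <- lapply(split(seq_along(g), ifelse(g, st$flag,
                                                paste0("not_", st$flag))),
                     function(i) km_estimate(tt[i], ee[i]))
    lr <- tryCatch(logrank_test(tt, ee, g), error = function(e) NULL)
    if (is.null(lr)) {
      note_skip(paste0("log-rank '", nm, "'"), "no events")
      next
    }
    km[[nm]] <- list(curves = curves, logrank = lr, n = sum(use))
  }

  roc <- cutoff <- NULL
  use_roc <- !is.na(prof$bmm) & !is.na(surv_onset$time) &
    !is.na(surv_onset$event)
  roc <- tryCatch(
    td_roc(prof$bmm[use_roc], surv_onset$time[use_roc],
           surv_onset$event[use_roc], config$thresholds$roc_horizon),
    error = function(e) { note_skip("BMM tdROC", conditionMessage(e)); NULL })
  if (!is.null(roc))
    cutoff <- select_cutoff(roc, config$roc_criterion,
                            preset = config$thresholds$bmm_cut)

  cox <- list()
  for (origin in config$origins) {
    ss <- survival_from(prof, origin)
    X <- prof[, config$cox_covariates, drop = FALSE]
    use <- stats::complete.cases(X) & !is.na(ss$time) & !is.na(ss$event)
    fit <- tryCatch(
      cox_fit(ss$time[use], ss$event[use], X[use, , drop = FALSE]),
      error = function(e) {
        note_skip(paste0("Cox model (", origin, ")"), conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) cox[[origin]] <- fit
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  structure(list(
    profiles = prof, excluded = excl$excluded, four_cell = four_cell,
    comparisons = comparisons, km = km, roc = roc, cutoff = cutoff,
    cox = cox, skipped = skipped,
    meta = list(config = config, config_hash = fnv1a(as.character(cfg_json)),
                package_version = as.character(utils::packageVersion("alsmet")),
                n_input = nrow(cohort), n_excluded = nrow(excl$excluded),
                n_analysed = nrow(prof))
  ), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("ALS metabolic-nutritional study: %d analysed (%d excluded)\n",
              x$meta$n_analysed, x$meta$n_excluded))
  cat("\nFour-cell stratification (complete BMI and mREE/LSTM):\n")
  print(x$four_cell)
  if (length(x$km)) {
    cat("\nLog-rank tests (survival from onset):\n")
    for (nm in names(x$km))
      cat(sprintf("  %-30s chi2 = %6.3f, p = %.4g (n = %d)\n", nm,
                  x$km[[nm]]$logrank$statistic, x$km[[nm]]$logrank$p.value,
                  x$km[[nm]]$n))
  }
  if (!is.null(x$roc)) {
    cat("\n"); print(x$roc)
    if (!is.null(x$cutoff)) print(x$cutoff)
  }
  for (origin in names(x$cox)) {
    cat(sprintf("\nCox model, survival from %s:\n", origin))
    print(x$cox[[origin]])
  }
  if (length(x$skipped)) {
    cat("\nSkipped analyses:\n")
    for (nm in names(x$skipped)) cat("  ", nm, ": ", x$skipped[nm], "\n")
  }
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Emits the augmented profile CSV, each comparison table as CSV and a
#' combined JSON, tidy KM curve CSVs, the ROC curve CSV plus a JSON
#' summary (AUC, chosen cutoff, sensitivity, specificity, horizon), the
#' Cox fits as covariate-keyed JSON, and a plain-text run log.
#'
#' @param result a `"study_result"`. @param dir output directory (created
#'   if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(dir, paste0(...))
  log_lines <- c(sprintf("alsmet %s run log", result$meta$package_version),
                 sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("config hash: %s", result$meta$config_hash),
                 sprintf("n input %d / excluded %d / analysed %d",
                         result$meta$n_input, result$meta$n_excluded,
                         result$meta$n_analysed))

  write_cohort(result$profiles, path("profiles.csv"))
  if (nrow(result$excluded))
    utils::write.csv(result$excluded, path("excluded.csv"), row.names = FALSE)

  for (nm in names(result$comparisons))
    utils::write.csv(result$comparisons[[nm]],
                     path("comparison_", nm, ".csv"), row.names = FALSE)
  jsonlite::write_json(result$comparisons, path("comparisons.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")

  for (nm in names(result$km)) {
    utils::write.csv(km_tidy(result$km[[nm]]$curves),
                     path("km_", nm, ".csv"), row.names = FALSE)
    lr <- result$km[[nm]]$logrank
    log_lines <- c(log_lines,
                   sprintf("log-rank %s: chi2 %.4f df %d p %.5g", nm,
                           lr$statistic, lr$df, lr$p.value))
  }

  if (!is.null(result$roc)) {
    utils::write.csv(result$roc$curve, path("roc_bmm.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      auc = result$roc$auc, horizon = result$roc$horizon,
      method = result$roc$method,
      cutoff = result$cutoff$cutoff,
      sensitivity = result$cutoff$sensitivity,
      specificity = result$cutoff$specificity,
      criterion = result$cutoff$criterion),
      path("roc_bmm.json"), auto_unbox = TRUE, digits = NA)
  }

  if (length(result$cox)) {
    cox_out <- lapply(result$cox, function(fit) {
      tab <- fit$coefficients
      stats::setNames(lapply(seq_len(nrow(tab)), function(i)
        as.list(tab[i, -1])), tab$term)
    })
    jsonlite::write_json(cox_out, path("cox.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }

  for (nm in names(result$skipped))
    log_lines <- c(log_lines,
                   sprintf("WARNING skipped %s: %s", nm, result$skipped[nm]))
  writeLines(log_lines, path("run.log"))
  invisible(dir)
}
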
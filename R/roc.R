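#' Time-dependent ROC curve for a survival outcome
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon: cases are
#' subjects reaching the endpoint by the horizon, controls are subjects
#' event-free beyond it. With `method = "km"` (default), censoring before
#' the horizon is handled by conditional Kaplan-Meier weighting: for each
#' cutoff c, sensitivity and specificity are built from the KM survival at
#' the horizon within `{marker > c}` and `{marker <= c}` and the overall
#' KM survival,
#' \deqn{sens(c) = \{1 - S(t | X > c)\} P(X > c) / \{1 - S(t)\},}
#' \deqn{spec(c) = S(t | X \le c) P(X \le c) / S(t).}
#' Raw conditional-KM estimates can be locally non-monotone under
#' censoring; estimates are clamped to \[0, 1\] and made monotone in the
#' cutoff by a cumulative-maximum pass (a no-op when nothing is censored
#' before the horizon, in which case the curve equals the plain empirical
#' ROC of the binary "event by horizon" label). `method = "empirical"`
#' computes that plain ROC directly, excluding subjects censored before
#' the horizon.
#'
#' Classification is `marker > cutoff`; the sweep covers every distinct
#' observed marker value plus -Inf (all positive) and +Inf (none).
#'
#' @param marker numeric marker values, complete for all included subjects.
#' @param time follow-up times. @param event logical event indicators.
#' @param horizon months (> 0).
#' @param method `"km"` or `"empirical"`.
#' @return object of class `"td_roc"`: list with `curve` (data frame:
#'   `cutoff, sensitivity, specificity`), `auc`, `horizon`, `method`,
#'   `n_cases`, `n_controls`.
#' @export
td_roc <- function(marker, time, event, horizon,
                   method = c("km", "empirical")) {
  method <- match.arg(method)
  if (anyNA(marker)) stop("marker must be complete for all included subjects")
  if (length(horizon) != 1L || !is.finite(horizon) || horizon <= 0)
    stop("horizon must be a positive number")
  if (anyNA(time) || anyNA(event)) stop("missing survival data")
  event <- as.logical(event)
  n <- length(marker)

  n_cases <- sum(time <= horizon & event)
  n_controls <- sum(time > horizon)
  if (n_cases == 0L || n_controls == 0L)
    stop("ROC curve undefined: no ", if (n_cases == 0L) "cases" else "controls",
         " at the horizon")

  cutoffs <- c(-Inf, sort(unique(marker)))

  if (method == "km") {
    S_all <- km_surv_at(km_estimate(time, event), horizon)
    if (S_all >= 1 || S_all <= 0)
      stop("ROC curve undefined: overall survival at the horizon is ",
           "degenerate")
    one <- function(co) {
      pos <- marker > co
      px <- mean(pos)
      if (px == 0) return(c(0, 1))
      if (px == 1) return(c(1, 0))
      S_pos <- km_surv_at(km_estimate(time[pos], event[pos]), horizon)
      S_neg <- km_surv_at(km_estimate(time[!pos], event[!pos]), horizon)
      sens <- (1 - S_pos) * px / (1 - S_all)
      spec <- S_neg * (1 - px) / S_all
      c(sens, spec)
    }
    pts <- t(vapply(cutoffs, one, numeric(2)))
    sens <- pmin(pmax(pts[, 1], 0), 1)
    spec <- pmin(pmax(pts[, 2], 0), 1)
    # enforce monotonicity in the cutoff (no-op without censoring)
    sens <- rev(cummax(rev(sens)))
    spec <- cummax(spec)
  } else {
    is_case <- time <= horizon & event
    is_control <- time > horizon
    keep <- is_case | is_control   # censored before horizon excluded
    m <- marker[keep]; case <- is_case[keep]
    sens <- vapply(cutoffs, function(co) mean(m[case] > co), numeric(1))
    spec <- vapply(cutoffs, function(co) mean(m[!case] <= co), numeric(1))
  }

  curve <- data.frame(cutoff = cutoffs, sensitivity = sens,
                      specificity = spec)
  res <- structure(list(curve = curve, horizon = horizon, method = method,
                        n_cases = n_cases, n_controls = n_controls),
                   class = "td_roc")
  res$auc <- roc_auc(res)
  res
}

#' Area under a ROC curve
#'
#' Trapezoidal integration of sensitivity over 1 - specificity, with the
#' (0, 0) and (1, 1) endpoints included.
#'
#' @param curve a `"td_roc"` object or a data frame with `sensitivity`
#'   and `specificity` columns.
#' @return the AUC in \[0, 1\].
#' @export
roc_auc <- function(curve) {
  if (inherits(curve, "td_roc")) curve <- curve$curve
  fpr <- 1 - curve$specificity
  sens <- curve$sensitivity
  if (length(fpr) < 2L && !(0 %in% fpr && 1 %in% fpr))
    stop("need at least two curve points")
  pts <- unique(rbind(data.frame(fpr = c(0, 1), sens = c(0, 1)),
                      data.frame(fpr = fpr, sens = sens)))
  pts <- pts[order(pts$fpr, pts$sens), ]
  sum(diff(pts$fpr) * (utils::head(pts$sens, -1) + utils::tail(pts$sens, -1)) / 2)
}

#' Select a marker cutoff from a ROC curve
#'
#' `criterion = "youden"` maximises sensitivity + specificity - 1 over
#' the finite observed cutoffs, breaking ties toward the smaller cutoff
#' (the -Inf/+Inf sweep endpoints are the degenerate all-positive /
#' all-negative rules and are not eligible). `criterion = "preset"`
#' reports the curve's operating point for the classification
#' `marker > preset`.
#'
#' @param curve a `"td_roc"` object.
#' @param criterion `"youden"` or `"preset"`.
#' @param preset the preset cutoff value (required when
#'   `criterion = "preset"`).
#' @return object of class `"cutoff_choice"`: list with `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, `criterion`.
#' @export
select_cutoff <- function(curve, criterion = c("youden", "preset"),
                          preset = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "td_roc"))
  tab <- curve$curve
  if (nrow(tab) == 0L) stop("empty ROC curve")
  if (criterion == "youden") {
    fin <- tab[is.finite(tab$cutoff), , drop = FALSE]
    if (nrow(fin) == 0L) stop("no finite cutoffs on the curve")
    J <- fin$sensitivity + fin$specificity - 1
    best <- which(J >= max(J) - 1e-12)
    i <- best[which.min(fin$cutoff[best])]
    out <- list(cutoff = fin$cutoff[i], sensitivity = fin$sensitivity[i],
                specificity = fin$specificity[i], youden = J[i],
                criterion = "youden")
  } else {
    if (is.null(preset)) stop("preset cutoff value required")
    # marker > preset is the rule of the largest stored cutoff <= preset
    idx <- max(which(tab$cutoff <= preset))
    out <- list(cutoff = preset, sensitivity = tab$sensitivity[idx],
                specificity = tab$specificity[idx],
                youden = tab$sensitivity[idx] + tab$specificity[idx] - 1,
                criterion = "preset")
  }
  structure(out, class = "cutoff_choice")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf(
    "Time-dependent ROC (%s) at %g months: AUC = %.3f (%d cases, %d controls)\n",
    x$method, x$horizon, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
print.cutoff_choice <- function(x, ...) {
  cat(sprintf("Cutoff %g (%s): sensitivity %.3f, specificity %.3f\n",
              x$cutoff, x$criterion, x$sensitivity, x$specificity))
  invisible(x)
}
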
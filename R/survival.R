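#' Survival samples from cohort records
#'
#' Builds (time, event) pairs from a cohort table, measuring time either
#' from symptom onset (`followup_months_from_onset`) or from the index
#' admission (`followup_months_from_onset - months_since_onset`). An
#' endpoint reached within the admission month gives a zero admission
#' duration; such durations are floored at `zero_floor` (default half a
#' month) so the subject enters the risk set, which is why admission-origin
#' survival curves can start below 100%.
#'
#' @param records cohort data frame (raw or profiled).
#' @param origin `"onset"` or `"admission"`.
#' @param zero_floor replacement for zero durations, months.
#' @return data frame with columns `time` (months) and `event` (logical).
#' @export
survival_from <- function(records, origin = c("onset", "admission"),
                          zero_floor = 0.5) {
  origin <- match.arg(origin)
  time <- switch(origin,
    onset = records$followup_months_from_onset,
    admission = records$followup_months_from_onset - records$months_since_onset)
  if (any(!is.na(time) & time < 0))
    stop("negative survival time: follow-up precedes the chosen origin")
  time[!is.na(time) & time == 0] <- zero_floor
  data.frame(time = time, event = as.logical(records$event))
}

#' Kaplan-Meier product-limit estimator
#'
#' Standard product-limit estimate. At a tied time, events are taken to
#' precede censorings (censored subjects at risk for that time's events).
#' The median is the smallest event time with S(t) <= 0.5, `NA` if the
#' curve never falls that low.
#'
#' @param time follow-up times (> 0).
#' @param event logical event indicators (`TRUE` = death/tracheostomy,
#'   `FALSE` = censored).
#' @return object of class `"km_curve"`: a list with a `table` data frame
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `surv` at each distinct
#'   event time), `n`, `n_event` and `median`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("no survival samples")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(is.na(time)) || any(is.na(event))) stop("missing survival data")
  if (any(time <= 0)) stop("survival times must be positive")
  event <- as.logical(event)

  etimes <- sort(unique(time[event]))
  n_risk <- vapply(etimes, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(etimes, function(t) sum(time == t & event), numeric(1))
  n_censor <- vapply(etimes, function(t) sum(time == t & !event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)

  med <- if (length(surv) && any(surv <= 0.5)) etimes[which(surv <= 0.5)[1]]
         else NA_real_
  structure(list(
    table = data.frame(time = etimes, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
    n = length(time), n_event = sum(event), median = med
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s months\n",
              x$n, x$n_event,
              if (is.na(x$median)) "not reached" else format(x$median)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# S(t) of a km_curve at an arbitrary time (right-continuous step function).
km_surv_at <- function(km, t) {
  tab <- km$table
  if (nrow(tab) == 0L) return(1)
  idx <- findInterval(t, tab$time)
  ifelse(idx == 0, 1, tab$surv[pmax(idx, 1)])
}

#' Log-rank test for k groups
#'
#' The standard O-E chi-square over pooled event times with the
#' hypergeometric variance (multi-event form at ties), df = groups - 1.
#'
#' @param time follow-up times. @param event logical event indicators.
#' @param group group labels (>= 2 non-empty groups).
#' @return object of class `"logrank_test"`: list with `statistic`, `df`,
#'   `p.value`, `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  keep <- !(is.na(time) | is.na(event) | is.na(group))
  time <- time[keep]; event <- as.logical(event[keep]); group <- group[keep]
  g <- factor(group)
  k <- nlevels(g)
  if (k < 2L) stop("log-rank test needs at least two groups")
  if (!any(event)) stop("log-rank statistic undefined: no events in any group")

  etimes <- sort(unique(time[event]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in etimes) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(time == t & event)
    n_ij <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    d_ij <- vapply(levels(g), function(l) sum(time == t & event & g == l),
                   numeric(1))
    O <- O + d_ij
    E <- E + d_j * n_ij / n_j
    if (n_j > 1) {
      mult <- d_j * (n_j - d_j) / (n_j - 1)
      p_i <- n_ij / n_j
      V <- V + mult * (diag(p_i, k) - tcrossprod(p_i))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vk, u)),
                   error = function(e) drop(t(u) %*% MASSless_ginv(Vk) %*% u))
  df <- k - 1L
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(g)),
                 expected = stats::setNames(E, levels(g))),
            class = "logrank_test")
}

# Moore-Penrose pseudoinverse via SVD, for a singular log-rank variance
# (degenerate risk sets); keeps the quadratic form well-defined.
MASSless_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d, 1)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = x$expected), row.names = FALSE)
  invisible(x)
}

#' Tidy export of Kaplan-Meier curves
#'
#' @param curves named list of `"km_curve"` objects (one per group).
#' @return data frame with columns `group, time, survival, at_risk, events`.
#' @export
km_tidy <- function(curves) {
  do.call(rbind, lapply(names(curves), function(nm) {
    tab <- curves[[nm]]$table
    data.frame(group = nm, time = tab$time, survival = tab$surv,
               at_risk = tab$n_risk, events = tab$n_event)
  }))
}
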
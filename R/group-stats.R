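#' @title Two-group comparison machinery
#' @description Fisher's exact test (minimum-likelihood two-sided
#'   convention), the Mann-Whitney U test (exact for small untied samples,
#'   tie- and continuity-corrected normal approximation otherwise),
#'   Spearman rank correlation and median \[IQR\] summaries -- the tests
#'   behind cohort characteristic tables.
#' @name group-stats
NULL

# log hypergeometric point probabilities over the support of cell `a`
# for a 2x2 table with row sums r1, r2 and first column sum c1.
hyper2x2_logprob <- function(r1, r2, c1) {
  a <- max(0L, c1 - r2):min(r1, c1)
  list(a = a,
       logp = lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1))
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Exact hypergeometric test with the minimum-likelihood two-sided
#' convention: the p-value sums the probabilities of every table with the
#' same margins whose point probability does not exceed that of the
#' observed table (up to a 1e-7 relative tolerance guarding equal
#' probabilities against floating-point noise).
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = group,
#'   columns = outcome yes/no), or the four counts `a, b, c, d` given as
#'   `table = a` with `b`, `c`, `d`.
#' @param b,c,d optional remaining cells when `table` is the scalar `a`.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(8, 3, 5, 13), 2, byrow = TRUE)) # 0.027
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) table <- matrix(c(table, b, c, d), 2, byrow = TRUE)
  if (!is.matrix(table) || any(dim(table) != 2))
    stop("need a 2x2 table of counts")
  if (anyNA(table) || any(table < 0) || any(table != round(table)))
    stop("cell counts must be non-negative integers")
  if (sum(table) == 0) stop("empty table")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  h <- hyper2x2_logprob(r1, r2, c1)
  logp_obs <- h$logp[h$a == table[1, 1]]
  rel <- 1 + 1e-7
  min(1, sum(exp(h$logp[h$logp <= logp_obs + log(rel)])))
}

# exact null distribution of the Mann-Whitney U statistic: number of
# rank arrangements with U = 0..n*m, by the standard count recursion
# f(n, m, u) = f(n-1, m, u-m) + f(n, m-1, u).
mwu_exact_counts <- function(n, m) {
  umax <- n * m
  # counts[i, j, ] built iteratively over i = 0..n as vectors over u
  prev <- matrix(0, m + 1L, umax + 1L)  # i = 0
  prev[, 1L] <- 1                        # f(0, j, 0) = 1
  for (i in seq_len(n)) {
    cur <- matrix(0, m + 1L, umax + 1L)
    cur[1L, 1L] <- 1                     # f(i, 0, 0) = 1
    for (j in seq_len(m)) {
      shifted <- c(rep(0, j), prev[j + 1L, seq_len(umax + 1L - j)])
      cur[j + 1L, ] <- shifted + cur[j, ]
    }
    prev <- cur
  }
  prev[m + 1L, ]
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. With both sample sizes at
#' most 10 and no ties, the two-sided p-value is exact (null permutation
#' distribution of U); otherwise a normal approximation with the tie
#' correction and a 0.5 continuity correction is used.
#'
#' @param x,y numeric samples; missing values are removed.
#' @return list with `statistic` (U for the first sample), `p.value`,
#'   `n_used` (the two sample sizes after missing-value removal) and
#'   `method` (`"exact"` or `"normal approximation"`).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)

  if (!has_ties && n1 <= 10L && n2 <= 10L) {
    counts <- mwu_exact_counts(n1, n2)
    total <- sum(counts)
    u_lo <- min(U, n1 * n2 - U)
    p <- min(1, 2 * sum(counts[seq_len(u_lo + 1L)]) / total)
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {           # every pooled value tied: no evidence
      z <- 0
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sigma
    }
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = U, p.value = p, n_used = c(n1, n2), method = method)
}

#' Spearman rank correlation
#'
#' Correlation of average ranks (tie-aware); the two-sided p-value uses
#' the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors; incomplete pairs are removed.
#' @return list with `statistic` (rs), `p.value`, `n_used`.
#' @export
spearman_rank <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector")
  rs <- stats::cor(rank(x), rank(y))
  if (abs(rs) >= 1) {
    p <- 0
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(statistic = rs, p.value = p, n_used = n)
}

#' Median and interquartile range
#'
#' Linear-interpolation (type-7) quantiles, the convention used for
#' median \[IQR\] reporting in cohort tables.
#'
#' @param values numeric vector; missing values removed.
#' @return named numeric vector `c(median, q1, q3)` (`NA`s if empty).
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Two-group characteristic comparison table
#'
#' For each variable, reports a per-group summary and the appropriate
#' test: continuous variables as median \[IQR\] with a Mann-Whitney U
#' p-value, binary/logical variables as positives/total with a Fisher
#' exact p-value. Missing values are deleted pairwise per variable, and
#' the per-group n actually used is reported.
#'
#' @param data data frame (typically a [classify_profile()] output).
#' @param group name of a logical (or two-level) grouping column.
#' @param variables character vector of column names to compare.
#' @return data frame of class `"group_comparison"` with one row per
#'   variable: `variable, type, summary_<levelA>, summary_<levelB>,
#'   n_<levelA>, n_<levelB>, p`.
#' @export
compare_groups <- function(data, group, variables) {
  if (!group %in% names(data)) stop("unknown grouping variable: ", group)
  unknown <- setdiff(variables, names(data))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  g <- data[[group]]
  lev <- sort(unique(g[!is.na(g)]))
  if (length(lev) != 2L)
    stop("grouping variable must have exactly two observed levels")

  rows <- lapply(variables, function(v) {
    val <- data[[v]]
    keep <- !is.na(val) & !is.na(g)
    val <- val[keep]; gg <- g[keep]
    in1 <- gg == lev[1]; in2 <- gg == lev[2]
    n1 <- sum(in1); n2 <- sum(in2)
    categorical <- is.logical(val) || is.character(val) || is.factor(val)
    if (categorical) {
      val <- as.logical(val)
      k1 <- sum(val[in1]); k2 <- sum(val[in2])
      s1 <- sprintf("%d/%d", k1, n1); s2 <- sprintf("%d/%d", k2, n2)
      p <- if (n1 > 0 && n2 > 0)
        fisher_exact_2x2(matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE))
      else NA_real_
      type <- "categorical"
    } else {
      f <- function(vv) {
        m <- median_iqr(vv)
        sprintf("%.3g [%.3g, %.3g]", m[1], m[2], m[3])
      }
      s1 <- if (n1) f(val[in1]) else ""
      s2 <- if (n2) f(val[in2]) else ""
      p <- if (n1 > 0 && n2 > 0)
        mann_whitney_u(val[in1], val[in2])$p.value else NA_real_
      type <- "continuous"
    }
    out <- data.frame(variable = v, type = type, s1 = s1, s2 = s2,
                      n1 = n1, n2 = n2, p = p, stringsAsFactors = FALSE)
    names(out)[3:6] <- c(paste0("summary_", lev), paste0("n_", lev))
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "group") <- group
  attr(res, "levels") <- lev
  class(res) <- c("group_comparison", "data.frame")
  res
}
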
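# Independent oracles used to check the package's native implementations.
# Deliberately naive: direct definitions, brute-force enumeration, grid
# search -- never the code paths under test.

# log partial likelihood (Breslow; equals Efron when no tied event times)
# for a single covariate vector, by the definition: at each event time,
# the subject's linear predictor minus log of the risk-set sum.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# two-stage grid maximisation of the partial likelihood; final
# resolution 5e-5 so agreement to 1e-4 is meaningful.
oracle_cox_grid <- function(time, event, x) {
  grid <- seq(-10, 10, by = 0.05)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1),
               time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.05, b0 + 0.05, by = 5e-5)
  llf <- vapply(fine, oracle_cox_loglik, numeric(1),
                time = time, event = event, x = x)
  fine[which.max(llf)]
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to the first sample (tie-free data only).
oracle_mwu_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  U_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  u_lo <- min(U_obs, n1 * n2 - U_obs)
  min(1, 2 * mean(U_all <= u_lo))
}

# plain empirical ROC of a binary label: sensitivity/specificity of the
# rule marker > c over all observed cutoffs plus -Inf, and its
# trapezoidal AUC.
oracle_plain_roc <- function(marker, label) {
  cutoffs <- c(-Inf, sort(unique(marker)))
  sens <- vapply(cutoffs, function(co) mean(marker[label] > co), numeric(1))
  spec <- vapply(cutoffs, function(co) mean(marker[!label] <= co), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  pts <- rbind(c(0, 0), cbind(fpr, sens)[ord, , drop = FALSE], c(1, 1))
  pts <- unique(pts)
  auc <- sum(diff(pts[, 1]) * (head(pts[, 2], -1) + tail(pts[, 2], -1)) / 2)
  list(cutoff = cutoffs, sensitivity = sens, specificity = spec, auc = auc)
}

# empirical survival function at the distinct event times (no censoring).
oracle_empirical_survival <- function(time) {
  t_sorted <- sort(unique(time))
  vapply(t_sorted, function(t) mean(time > t), numeric(1))
}

# small exponential two-group survival dataset, continuous times (no ties)
make_surv_data <- function(n, beta, event_frac = 0.8) {
  x <- rep(c(0, 1), length.out = n)
  t_death <- rexp(n, rate = 0.1 * exp(beta * x))
  cens <- rexp(n, rate = 0.1 * (1 - event_frac) / event_frac)
  data.frame(time = pmin(t_death, cens), event = t_death <= cens, x = x)
}

# minimal valid raw cohort table built by hand for unit tests
make_records <- function(n = 6) {
  data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    age = seq(55, by = 3, length.out = n),
    sex = rep(c("M", "F"), length.out = n),
    height = rep(c(1.70, 1.55), length.out = n),
    premorbid_weight = rep(c(65, 52), length.out = n),
    admission_weight = rep(c(60, 48), length.out = n),
    months_since_onset = rep(c(10, 20), length.out = n),
    months_since_first_visit = rep(2, n),
    alsfrs_r = rep(c(40, 36), length.out = n),
    bulbar_onset = rep(c(FALSE, TRUE), length.out = n),
    vo2 = rep(c(240, 200), length.out = n),
    vco2 = rep(c(200, 165), length.out = n),
    lstm = rep(c(40, 28), length.out = n),
    body_fat_pct = rep(c(24, 33), length.out = n),
    smi = rep(c(6.5, 5.0), length.out = n),
    fbs = rep(c(95, 102), length.out = n),
    ldl = rep(c(98, 120), length.out = n),
    pef_pct = rep(c(80, 70), length.out = n),
    vc_pct = rep(c(90, 82), length.out = n),
    peg = rep(c(FALSE, TRUE), length.out = n),
    nppv = rep(FALSE, n),
    followup_months_from_onset = seq(24, by = 4, length.out = n),
    event = rep(c(TRUE, FALSE), length.out = n),
    stringsAsFactors = FALSE
  )
}
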
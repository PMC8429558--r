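#' Cox proportional-hazards model
#'
#' Newton-Raphson maximisation of the partial likelihood with the Efron
#' (default) or Breslow treatment of tied event times. Convergence is
#' declared when the largest score component or the largest coefficient
#' change falls below `tol`; at most `max_iter` iterations with step
#' halving if the partial likelihood fails to increase.
#'
#' Wald inference: standard errors from the inverse observed information,
#' hazard ratios `exp(coef)`, 95% confidence limits `exp(coef +/- 1.96 se)`
#' and two-sided normal p-values. Zero-variance covariates carry no
#' information: their coefficient is pinned at 0 with `NA` standard error
#' (with a warning). Collinear covariates are a rank-deficient design and
#' raise an error. A fit whose scaled coefficients run away (monotone
#' partial likelihood, e.g. complete separation of event order by a binary
#' covariate) is returned with `converged = FALSE` and `diverging = TRUE`
#' plus a warning, never silently.
#'
#' @param time follow-up times (> 0). @param event logical event indicators.
#' @param x covariate vector, matrix or data frame (no missing values;
#'   drop incomplete rows upstream). Logical columns are coerced to 0/1.
#' @param ties `"efron"` or `"breslow"`.
#' @param tol convergence tolerance (default 1e-9).
#' @param max_iter iteration cap (default 50).
#' @return object of class `"cox_fit"`: list with `coefficients` (data
#'   frame: term, coef, se, hr, ci_low, ci_high, z, p), `loglik`,
#'   `loglik_null`, `iterations`, `converged`, `diverging`, `ties`, `n`,
#'   `n_event`.
#' @export
cox_fit <- function(time, event, x, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(time)
  if (nrow(x) != n || length(event) != n) stop("input lengths differ")
  if (anyNA(time) || anyNA(event) || anyNA(x))
    stop("missing values in survival data or covariates; drop incomplete rows first")
  if (any(time <= 0)) stop("survival times must be positive")
  event <- as.logical(event)
  if (!any(event)) stop("no events; partial likelihood undefined")

  xsd <- apply(x, 2, stats::sd)
  active <- xsd > 0
  if (!all(active))
    warning("covariate(s) constant across subjects, no information: ",
            paste(colnames(x)[!active], collapse = ", "))
  xa <- x[, active, drop = FALSE]
  p <- ncol(xa)
  if (p > 0 && qr(scale(xa, scale = FALSE))$rank < p)
    stop("rank-deficient covariate matrix (collinear covariates): ",
         paste(colnames(xa), collapse = ", "))

  centers <- if (p) colMeans(xa) else numeric(0)
  xc <- if (p) sweep(xa, 2, centers) else xa
  etimes <- sort(unique(time[event]))
  risk_idx <- lapply(etimes, function(t) which(time >= t))
  death_idx <- lapply(etimes, function(t) which(time == t & event))

  # log partial likelihood, score and information at beta
  eval_at <- function(beta, need_deriv = TRUE) {
    eta <- drop(xc %*% beta)
    w <- exp(eta)
    ll <- 0
    U <- numeric(p)
    I <- matrix(0, p, p)
    for (j in seq_along(etimes)) {
      R <- risk_idx[[j]]; D <- death_idx[[j]]; d <- length(D)
      wR <- w[R]; xR <- xc[R, , drop = FALSE]
      S0 <- sum(wR)
      S1 <- drop(crossprod(xR, wR))
      if (need_deriv) S2 <- crossprod(xR, wR * xR)
      if (ties == "efron" && d > 1) {
        wD <- w[D]; xD <- xc[D, , drop = FALSE]
        S0D <- sum(wD)
        S1D <- drop(crossprod(xD, wD))
        if (need_deriv) S2D <- crossprod(xD, wD * xD)
      } else {
        S0D <- 0; S1D <- numeric(p)
        if (need_deriv) S2D <- matrix(0, p, p)
      }
      ll <- ll + sum(eta[D])
      if (need_deriv) U <- U + colSums(xc[D, , drop = FALSE])
      fr <- if (ties == "efron") (seq_len(d) - 1) / d else numeric(d)
      for (f in fr) {
        phi <- S0 - f * S0D
        ll <- ll - log(phi)
        if (need_deriv) {
          m <- (S1 - f * S1D) / phi
          U <- U - m
          I <- I + (S2 - f * S2D) / phi - tcrossprod(m)
        }
      }
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- numeric(p)
  iter <- 0L
  converged <- FALSE
  diverging <- FALSE
  ev <- eval_at(beta)
  loglik_null <- if (p) eval_at(numeric(p), need_deriv = FALSE)$ll else ev$ll
  if (p == 0) {
    converged <- TRUE
  } else {
    repeat {
      iter <- iter + 1L
      step <- tryCatch(solve(ev$I, ev$U), error = function(e) NULL)
      if (is.null(step)) {  # singular information (flat direction)
        if (max(abs(ev$U)) < tol) { converged <- TRUE; break }
        step <- drop(MASSless_ginv(ev$I) %*% ev$U)
      }
      new_beta <- beta + step
      new_ev <- eval_at(new_beta)
      halvings <- 0L
      while ((!is.finite(new_ev$ll) || new_ev$ll < ev$ll - 1e-12) &&
             halvings < 25L) {
        halvings <- halvings + 1L
        new_beta <- beta + (new_beta - beta) / 2
        new_ev <- eval_at(new_beta)
      }
      delta <- max(abs(new_beta - beta))
      beta <- new_beta; ev <- new_ev
      if (max(abs(ev$U)) < tol || delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    if (max(abs(beta * xsd[active])) > 10) {
      diverging <- TRUE
      converged <- FALSE
      warning("monotone partial likelihood: coefficient(s) diverging ",
              "(complete or quasi-complete separation)")
    } else if (!converged) {
      warning("Cox fit did not converge in ", max_iter, " iterations")
    }
  }

  se_a <- rep(NA_real_, p)
  if (p) {
    var_a <- tryCatch(solve(ev$I), error = function(e) NULL)
    if (is.null(var_a)) {
      warning("singular information matrix; standard errors unavailable")
    } else se_a <- sqrt(pmax(diag(var_a), 0))
  }

  coef_full <- se_full <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
  coef_full[active] <- beta
  coef_full[!active] <- 0
  se_full[active] <- se_a
  z <- coef_full / se_full
  tab <- data.frame(
    term = colnames(x),
    coef = unname(coef_full),
    se = unname(se_full),
    hr = unname(exp(coef_full)),
    ci_low = unname(exp(coef_full - 1.96 * se_full)),
    ci_high = unname(exp(coef_full + 1.96 * se_full)),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = tab, loglik = ev$ll,
                 loglik_null = loglik_null, iterations = iter,
                 converged = converged, diverging = diverging, ties = ties,
                 n = n, n_event = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  cat(sprintf("log partial likelihood %.4f (null %.4f), %d iterations%s\n",
              x$loglik, x$loglik_null, x$iterations,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
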
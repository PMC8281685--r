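# Newton-Raphson maximization of the Breslow partial likelihood.
#
# The risk set at an event time t contains every sample with follow-up >= t;
# tied event times share one risk-set denominator (Breslow). Everything is
# vectorized over a single descending time sort, so per-iteration cost is
# O(n p^2) with small p (the screen uses p = 1, multivariable fits a handful).

# Precompute the sort order and tie structure once so the per-pair screen can
# reuse it across thousands of fits.
cox_prepare <- function(time, event) {
  stopifnot(length(time) == length(event))
  o <- order(time, decreasing = TRUE)
  t_sorted <- time[o]
  # last index of each tie run = index whose cumulative sums cover the whole
  # risk set {time >= t}
  r <- rle(t_sorted)
  last_idx <- rep(cumsum(r$lengths), times = r$lengths)
  list(order = o, event = as.numeric(event[o]), last = last_idx,
       n = length(time), n_events = sum(event != 0))
}

# Breslow partial log-likelihood, gradient and information at beta.
cox_derivatives <- function(beta, X, prep) {
  w <- as.vector(exp(X %*% beta))
  d <- prep$event
  ev <- d == 1
  S0 <- cumsum(w)[prep$last]
  p <- ncol(X)
  S1 <- matrix(0, prep$n, p)
  for (j in seq_len(p)) S1[, j] <- cumsum(w * X[, j])[prep$last]
  loglik <- sum((X[ev, , drop = FALSE] %*% beta)) - sum(log(S0[ev]))
  xbar <- S1 / S0
  U <- colSums(X[ev, , drop = FALSE] - xbar[ev, , drop = FALSE])
  I <- matrix(0, p, p)
  for (j in seq_len(p)) {
    for (k in j:p) {
      S2jk <- cumsum(w * X[, j] * X[, k])[prep$last]
      v <- sum(S2jk[ev] / S0[ev] - xbar[ev, j] * xbar[ev, k])
      I[j, k] <- v
      I[k, j] <- v
    }
  }
  list(loglik = loglik, U = U, I = I)
}

# Core fitter. X: n x p numeric matrix (caller-validated). Returns beta, se,
# loglik at convergence, the score test at beta = 0, and iteration count.
cox_fit_engine <- function(X, time, event, max_iter = 100, grad_tol = 1e-8,
                           term_names = colnames(X)) {
  if (is.null(term_names)) term_names <- paste0("x", seq_len(ncol(X)))
  prep <- cox_prepare(time, event)
  if (prep$n_events == 0) stopf("no events in the survival data")
  Xo <- X[prep$order, , drop = FALSE]
  p <- ncol(Xo)
  beta <- rep(0, p)

  d0 <- cox_derivatives(beta, Xo, prep)
  score_stat <- tryCatch(
    as.numeric(t(d0$U) %*% solve(d0$I, d0$U)),
    error = function(e) NA_real_
  )

  dv <- d0
  converged <- max(abs(dv$U)) < grad_tol
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(dv$I, dv$U), error = function(e) NULL)
    if (is.null(step)) {
      stopf("Cox fit failed: singular information matrix (covariate '%s')",
            term_names[which.max(abs(dv$U))])
    }
    # step-halving keeps the partial likelihood monotone
    new_beta <- beta + step
    new_dv <- cox_derivatives(new_beta, Xo, prep)
    halvings <- 0L
    while ((!is.finite(new_dv$loglik) || new_dv$loglik < dv$loglik - 1e-12) &&
           halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_dv <- cox_derivatives(new_beta, Xo, prep)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    dv <- new_dv
    if (any(abs(beta) > 15)) {
      stopf(
        "Cox fit failed: monotone likelihood / separation for covariate '%s'",
        term_names[which.max(abs(beta))]
      )
    }
    converged <- max(abs(dv$U)) < grad_tol
  }
  if (!converged) {
    stopf("Cox fit did not converge in %d iterations (covariate '%s')",
          max_iter, term_names[which.max(abs(dv$U))])
  }
  se <- sqrt(diag(solve(dv$I)))
  list(coef = stats::setNames(beta, term_names),
       se = stats::setNames(se, term_names),
       loglik = dv$loglik, loglik_null = d0$loglik,
       score_test = score_stat, iter = iter, n = prep$n,
       n_events = prep$n_events)
}
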
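# Independent brute-force oracles used to validate the analytical
# implementations. Deliberately naive: explicit loops, no shared code with
# the package internals.

# Breslow partial log-likelihood by direct summation over events.
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Maximize by coarse grid then golden-section refinement; returns the
# estimate, a finite-difference SE and the Wald p-value.
oracle_cox_fit <- function(x, time, event) {
  grid <- seq(-10, 10, by = 0.01)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), x = x, time = time,
               event = event)
  b0 <- grid[which.max(ll)]
  opt <- stats::optimize(function(b) -oracle_cox_loglik(b, x, time, event),
                         c(b0 - 0.02, b0 + 0.02), tol = 1e-9)
  b <- opt$minimum
  h <- 1e-4
  d2 <- (oracle_cox_loglik(b + h, x, time, event) -
           2 * oracle_cox_loglik(b, x, time, event) +
           oracle_cox_loglik(b - h, x, time, event)) / h^2
  se <- 1 / sqrt(-d2)
  list(beta = b, se = se, p = 2 * stats::pnorm(-abs(b / se)))
}

# Log-rank by direct evaluation of O - E and the hypergeometric variance at
# every distinct observed time.
oracle_logrank <- function(time, event, in_group1) {
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time))) {
    n <- 0; n1 <- 0; d <- 0; d1 <- 0
    for (i in seq_along(time)) {
      if (time[i] >= t) {
        n <- n + 1
        if (in_group1[i]) n1 <- n1 + 1
      }
      if (time[i] == t && event[i] == 1) {
        d <- d + 1
        if (in_group1[i]) d1 <- d1 + 1
      }
    }
    if (d > 0) {
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  (O - E)^2 / V
}

# Mann-Whitney statistic (ties get weight 1/2) of marker values for cases
# versus controls.
oracle_mann_whitney <- function(case_scores, control_scores) {
  tot <- 0
  for (u in case_scores) {
    for (v in control_scores) {
      tot <- tot + (u > v) + 0.5 * (u == v)
    }
  }
  tot / (length(case_scores) * length(control_scores))
}

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, probabilities from log-factorials.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  tab_prob <- function(x) {
    exp(lfactorial(m) + lfactorial(n2) + lfactorial(k) + lfactorial(N - k) -
          lfactorial(N) - lfactorial(x) - lfactorial(m - x) -
          lfactorial(k - x) - lfactorial(n2 - k + x))
  }
  p_obs <- tab_prob(a)
  total <- 0
  for (x in max(0, k - n2):min(k, m)) {
    px <- tab_prob(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  min(total, 1)
}

# Exponential-baseline cohort with an independent marker and uniform
# censoring; shared by the null-calibration tests.
make_null_surv <- function(n, censoring = 0.3, rate = 1 / 1000) {
  t_event <- stats::rexp(n, rate)
  f <- function(cmax) mean(pmin(t_event / cmax, 1)) - censoring
  c_max <- stats::uniroot(f, c(1e-3, 1e9))$root
  c_time <- stats::runif(n, 0, c_max)
  data.frame(sample = sprintf("S%04d", seq_len(n)),
             time = pmin(t_event, c_time),
             event = as.integer(t_event <= c_time),
             stringsAsFactors = FALSE)
}
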
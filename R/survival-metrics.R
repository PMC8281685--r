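# Censored-survival evaluation: Kaplan-Meier, log-rank, Cox PH,
# time-dependent ROC and ROC-derived cutoff selection.

validate_survival <- function(surv) {
  if (!is.data.frame(surv) || !all(c("time", "event") %in% names(surv))) {
    stopf("survival data must be a data.frame with 'time' and 'event' columns")
  }
  if (any(!is.finite(surv$time)) || any(surv$time <= 0)) {
    stopf("survival times must be finite and > 0")
  }
  if (!all(surv$event %in% c(0, 1))) stopf("event indicator must be 0/1")
  invisible(surv)
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function S(t) under right censoring. Censored
#' follow-up times reduce the risk set without introducing a step; tied event
#' times produce a single step.
#'
#' @param surv data.frame with columns `time` (> 0) and `event` (1 = death
#'   observed, 0 = censored).
#' @return An object of class `km_curve`: a data.frame with one row per
#'   distinct event time, columns `time`, `n_risk`, `n_event`, `surv`
#'   (the estimate immediately after the step). All-censored input yields a
#'   zero-row curve, i.e. S identically 1.
#' @seealso [km_at()] to evaluate the step function, [logrank_test()]
#' @examples
#' km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(0, 1, 1)))
#' km_at(km, 2)  # 0.5
#' @export
km_estimate <- function(surv) {
  validate_survival(surv)
  times <- sort(unique(surv$time[surv$event == 1]))
  n_risk <- vapply(times, function(t) sum(surv$time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(surv$time == t & surv$event == 1),
                    numeric(1))
  s <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = times, n_risk = n_risk, n_event = n_event, surv = s)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step evaluation: S(t) = 1 before the first event.
#'
#' @param km a [km_estimate()] result.
#' @param t numeric vector of evaluation times.
#' @return numeric vector of survival probabilities.
#' @export
km_at <- function(km, t) {
  if (nrow(km) == 0) return(rep(1, length(t)))
  vapply(t, function(ti) {
    i <- findInterval(ti, km$time)
    if (i == 0) 1 else km$surv[i]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard O - E statistic with hypergeometric variance, accumulated over the
#' distinct event times, referred to a 1-df chi-square distribution.
#'
#' @param surv data.frame with columns `time` and `event`.
#' @param groups two-level factor/vector of group labels, aligned with `surv`
#'   rows.
#' @return list with `statistic` (chi-square), `p_value`, `observed` and
#'   `expected` event counts for the first group level.
#' @export
logrank_test <- function(surv, groups) {
  validate_survival(surv)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) {
    stopf("log-rank test requires exactly 2 non-empty groups (got %d)",
          nlevels(droplevels(groups)))
  }
  groups <- droplevels(groups)
  if (sum(surv$event) == 0) stopf("log-rank test requires at least one event")
  g1 <- groups == levels(groups)[1]
  times <- sort(unique(surv$time[surv$event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- surv$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(surv$time == t & surv$event == 1)
    d1 <- sum(surv$time == t & surv$event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson to a gradient
#' norm below 1e-8. Confidence intervals use the normal approximation on the
#' log-hazard scale, exp(beta +/- 1.96 se).
#'
#' @param surv data.frame with `time`, `event` and any covariate columns.
#' @param covariates character vector of covariate column names in `surv`, or
#'   a numeric data.frame/matrix aligned with `surv` rows.
#' @return data.frame with one row per covariate: `term`, `coef`, `hr`,
#'   `ci_lower`, `ci_upper`, `se`, `p_value` (Wald). Attributes `loglik`,
#'   `n`, `n_events`.
#' @examples
#' sim <- simulate_cohort(n_samples = 120, seed = 7)
#' cl <- sim$clinical
#' cl$x <- rnorm(nrow(cl))
#' fit_cox(cl, "x")
#' @export
fit_cox <- function(surv, covariates) {
  validate_survival(surv)
  if (is.character(covariates)) {
    missing_cov <- setdiff(covariates, names(surv))
    if (length(missing_cov)) {
      stopf("covariate column(s) not found: %s",
            paste(missing_cov, collapse = ", "))
    }
    X <- as.matrix(surv[covariates])
  } else {
    X <- as.matrix(covariates)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (!is.numeric(X) || anyNA(X)) stopf("covariates must be numeric, no NA")
  const <- apply(X, 2, function(v) length(unique(v)) < 2)
  if (any(const)) {
    stopf("constant covariate(s): %s",
          paste(colnames(X)[const], collapse = ", "))
  }
  fit <- cox_fit_engine(X, surv$time, surv$event)
  z <- fit$coef / fit$se
  out <- data.frame(
    term = names(fit$coef),
    coef = unname(fit$coef),
    hr = exp(unname(fit$coef)),
    ci_lower = exp(unname(fit$coef) - 1.96 * unname(fit$se)),
    ci_upper = exp(unname(fit$coef) + 1.96 * unname(fit$se)),
    se = unname(fit$se),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  attr(out, "loglik") <- fit$loglik
  attr(out, "score_test") <- fit$score_test
  attr(out, "n") <- fit$n
  attr(out, "n_events") <- fit$n_events
  out
}

#' Time-dependent ROC curve (cumulative cases / dynamic controls)
#'
#' ROC at horizon t* with cases = subjects with an event by t* and controls =
#' subjects event-free past t*, estimated under censoring by Kaplan-Meier
#' conditioning: with S the KM estimate,
#' sensitivity(c) = (1 - S(t* | X > c)) P(X > c) / (1 - S(t*)) and
#' specificity(c) = S(t* | X <= c) P(X <= c) / S(t*), evaluated at every
#' observed marker value. AUC by the trapezoidal rule.
#'
#' @param scores numeric marker, higher = higher predicted risk.
#' @param surv data.frame with `time` and `event`, aligned with `scores`.
#' @param horizon evaluation time t*, inside the observed follow-up.
#' @return object of class `td_roc`: list with `horizon`, `thresholds`
#'   (descending, last = -Inf), `sensitivity`, `specificity`, `auc`.
#' @export
time_dependent_roc <- function(scores, surv, horizon) {
  validate_survival(surv)
  stopifnot(length(scores) == nrow(surv), is.finite(horizon))
  if (!any(surv$time <= horizon & surv$event == 1)) {
    stopf("no events observed at or before horizon %g", horizon)
  }
  s_all <- km_at(km_estimate(surv), horizon)
  if (s_all <= 0) stopf("no survivors beyond horizon %g", horizon)
  thresholds <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  n <- length(scores)
  sens <- numeric(length(thresholds))
  spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    hi <- scores > thresholds[i]
    p_hi <- mean(hi)
    s_hi <- if (any(hi)) km_at(km_estimate(surv[hi, , drop = FALSE]), horizon) else 1
    s_lo <- if (any(!hi)) km_at(km_estimate(surv[!hi, , drop = FALSE]), horizon) else 1
    sens[i] <- (1 - s_hi) * p_hi / (1 - s_all)
    spec[i] <- s_lo * (1 - p_hi) / s_all
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  # integrate in descending-threshold order (fpr nondecreasing up to KM
  # estimation noise); signed trapezoid keeps the uncensored case exact
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(horizon = horizon, thresholds = thresholds,
                 sensitivity = sens, specificity = spec, auc = auc),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC (KM conditioning), horizon %g: AUC = %.4f (%d thresholds)\n",
              x$horizon, x$auc, length(x$thresholds)))
  invisible(x)
}

#' Select a classification cutoff from a time-dependent ROC curve
#'
#' Returns the finite threshold maximizing Youden's J = sensitivity +
#' specificity - 1, breaking ties toward the smallest threshold. A flat curve
#' (all J equal) returns the smallest finite threshold with a warning.
#'
#' @param roc a [time_dependent_roc()] result.
#' @return the selected cutoff (numeric scalar).
#' @export
select_cutoff <- function(roc) {
  stopifnot(inherits(roc, "td_roc"))
  finite <- is.finite(roc$thresholds)
  if (!any(finite)) stopf("ROC curve has no finite thresholds")
  thr <- roc$thresholds[finite]
  J <- roc$sensitivity[finite] + roc$specificity[finite] - 1
  if (diff(range(J)) < .Machine$double.eps^0.5) {
    warnf("flat ROC curve: all thresholds have equal Youden's J; returning smallest")
    return(min(thr))
  }
  best <- which(J == max(J))
  min(thr[best])
}
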
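# Kaplan-Meier, log-rank, Cox PH, time-dependent ROC, cutoff selection.

test_that("product-limit estimate matches hand calculation and its limits", {
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(0, 1, 1)))
  expect_equal(km_at(km, 2), 0.5)
  expect_equal(km_at(km, 3), 0)
  expect_equal(km_at(km, 1.5), 1)  # no step before the first event

  # no censoring: S(t) equals the empirical fraction of times > t
  withr::with_seed(1, t_obs <- round(rexp(40, 1 / 50), 2))
  km2 <- km_estimate(data.frame(time = t_obs, event = 1L))
  for (t in c(5, 20, 50, 120)) {
    expect_equal(km_at(km2, t), mean(t_obs > t))
  }
  expect_true(all(diff(km2$surv) <= 0))

  # all censored: S identically 1
  km3 <- km_estimate(data.frame(time = c(3, 8), event = 0L))
  expect_equal(km_at(km3, c(1, 5, 100)), c(1, 1, 1))
})

test_that("log-rank matches the brute-force O-E oracle and the Cox score test", {
  surv <- data.frame(time = c(1, 2, 3, 10, 11, 12), event = 1L)
  g <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(surv, g)
  expect_equal(lr$statistic, oracle_logrank(surv$time, surv$event, g == "a"),
               tolerance = 1e-10)

  withr::with_seed(5, {
    surv2 <- make_null_surv(80)
    surv2$time <- surv2$time + runif(80, 0, 1e-3)  # enforce tie-free times
    g2 <- rep(c("a", "b"), 40)
    lr2 <- logrank_test(surv2, g2)
    expect_equal(lr2$statistic,
                 oracle_logrank(surv2$time, surv2$event, g2 == "a"),
                 tolerance = 1e-10)
    cox <- irgpair:::cox_fit_engine(matrix(as.numeric(g2 == "a")),
                                    surv2$time, surv2$event)
    expect_equal(lr2$statistic, cox$score_test, tolerance = 1e-8)
  })
})

test_that("log-rank is symmetric in group labels and degenerate for identical groups", {
  withr::with_seed(6, surv <- make_null_surv(60))
  g <- rep(c("x", "y"), 30)
  lr_xy <- logrank_test(surv, g)
  lr_yx <- logrank_test(surv, rev(g))
  expect_equal(lr_xy$statistic, lr_yx$statistic)
  expect_true(lr_xy$p_value >= 0 && lr_xy$p_value <= 1)

  # duplicated data split into two identical groups: O = E exactly
  base <- data.frame(time = c(2, 4, 6, 8), event = c(1L, 1L, 0L, 1L))
  both <- rbind(base, base)
  lr0 <- logrank_test(both, rep(c("a", "b"), each = 4))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)

  expect_error(logrank_test(base, rep("a", 4)), "2 non-empty groups")
})

test_that("Cox fit matches the grid-search oracle and survival::coxph", {
  surv <- data.frame(time = c(2, 5, 7, 9), event = 1L)
  x <- c(1, 0, 1, 0)
  fit <- fit_cox(cbind(surv, x = x), "x")
  orc <- oracle_cox_fit(x, surv$time, surv$event)
  expect_equal(fit$coef, orc$beta, tolerance = 1e-5)
  expect_equal(fit$p_value, orc$p, tolerance = 1e-5)

  # independent cross-check against the reference implementation
  withr::with_seed(8, {
    surv2 <- make_null_surv(100)
    surv2$z <- rnorm(100)
    surv2$w <- rbinom(100, 1, 0.4)
  })
  fit2 <- fit_cox(surv2, c("z", "w"))
  ref <- survival::coxph(survival::Surv(time, event) ~ z + w, data = surv2,
                         ties = "breslow")
  expect_equal(fit2$coef, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit2$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("Cox CI covers the null and the true beta at nominal rates", {
  covered_null <- 0
  for (seed in 1:20) {
    withr::with_seed(seed, {
      surv <- make_null_surv(1000)
      surv$x <- rnorm(1000)
    })
    fit <- fit_cox(surv, "x")
    if (fit$ci_lower <= 1 && 1 <= fit$ci_upper) covered_null <- covered_null + 1
  }
  expect_gte(covered_null, 18)  # >= 90% of 20 seeds

  # proportional-hazards recovery on simulated cohorts: beta within 2 SE
  covered <- 0; total <- 0
  for (seed in 1:10) {
    sim <- simulate_cohort(n_samples = 500, seed = seed)
    x <- t((sim$expression[sim$truth$gene_a, ] >
              sim$expression[sim$truth$gene_b, ]) * 1)
    colnames(x) <- sim$truth$pair_id
    fit <- fit_cox(cbind(sim$clinical[c("time", "event")],
                         as.data.frame(x)),
                   sim$truth$pair_id)
    covered <- covered + sum(abs(fit$coef - sim$truth$beta) <= 2 * fit$se)
    total <- total + nrow(fit)
  }
  expect_gte(covered / total, 0.9)
})

test_that("Cox fit rejects constant covariates and separation", {
  surv <- data.frame(time = 1:6, event = 1L, k = 1, s = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_cox(surv, "k"), "constant")
  # perfectly separating covariate: monotone likelihood
  expect_error(fit_cox(surv, "s"), "separation")
})

test_that("time-dependent ROC: perfect marker, Mann-Whitney reduction, negation", {
  withr::with_seed(11, {
    t_obs <- sort(runif(30, 10, 100))
    surv <- data.frame(time = t_obs, event = 1L)
  })
  # marker = -time ranks everyone perfectly at any horizon between times
  roc <- time_dependent_roc(-t_obs, surv, horizon = 55)
  expect_equal(roc$auc, 1)

  withr::with_seed(12, {
    marker <- rnorm(60)
    surv2 <- data.frame(time = rexp(60, 1 / 40) + marker, event = 1L)
    surv2$time <- pmax(surv2$time, 0.1)
  })
  horizon <- stats::median(surv2$time)
  roc2 <- time_dependent_roc(marker, surv2, horizon)
  mw <- oracle_mann_whitney(marker[surv2$time <= horizon],
                            marker[surv2$time > horizon])
  expect_equal(roc2$auc, mw, tolerance = 1e-10)

  # AUC(-marker) = 1 - AUC(marker) on tie-free data
  roc_neg <- time_dependent_roc(-marker, surv2, horizon)
  expect_equal(roc_neg$auc, 1 - roc2$auc, tolerance = 1e-10)

  # curve endpoints in (1 - spec, sens) space
  expect_equal(min(roc2$sensitivity), 0)
  expect_equal(max(roc2$sensitivity), 1)
  expect_error(time_dependent_roc(marker, surv2, horizon = 1e-6),
               "no events")
})

test_that("cutoff selection maximizes Youden's J with documented tie-breaks", {
  roc <- structure(list(horizon = 365, thresholds = c(3, 2, 1),
                        sensitivity = c(0.2, 0.8, 0.9),
                        specificity = c(0.9, 0.8, 0.4),
                        auc = NA_real_), class = "td_roc")
  expect_equal(select_cutoff(roc), 2)  # J = {0.1, 0.6, 0.3}

  flat <- structure(list(horizon = 365, thresholds = c(3, 2, 1, -Inf),
                         sensitivity = c(0.25, 0.5, 0.75, 1),
                         specificity = c(0.75, 0.5, 0.25, 0),
                         auc = 0.5), class = "td_roc")
  expect_warning(cut <- select_cutoff(flat), "flat")
  expect_equal(cut, 1)

  # perfectly separable marker: selected cutoff separates, J = 1
  surv <- data.frame(time = c(5, 6, 7, 50, 60, 70), event = 1L)
  scores <- c(10, 11, 12, 1, 2, 3)
  roc2 <- time_dependent_roc(scores, surv, horizon = 20)
  cut2 <- select_cutoff(roc2)
  expect_true(cut2 >= 3 && cut2 < 10)
  i <- which(roc2$thresholds == cut2)
  expect_equal(roc2$sensitivity[i] + roc2$specificity[i] - 1, 1)
})
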
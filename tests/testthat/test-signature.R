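# Univariate screen, penalized fit, scoring, classification, serialization.

toy_profile <- function(x, sample_ids = paste0("S", seq_along(x))) {
  v <- matrix(as.integer(x), nrow = 1, dimnames = list(NULL, sample_ids))
  as_pair_profile(v, "A", "B")
}

test_that("screen Wald statistics match the grid-search partial-likelihood oracle", {
  surv <- data.frame(sample = paste0("S", 1:4), time = c(1, 2, 3, 4),
                     event = 1L)
  x <- c(1, 0, 1, 0)  # interleaved: interior partial-likelihood maximum
  res <- univariate_screen(toy_profile(x), surv)
  orc <- oracle_cox_fit(x, surv$time, surv$event)
  expect_equal(res$coef, orc$beta, tolerance = 1e-5)
  expect_equal(res$p_value, orc$p, tolerance = 1e-5)
  expect_equal(res$hr, exp(orc$beta), tolerance = 1e-5)
  expect_true(res$ci_lower < res$hr && res$hr < res$ci_upper)
})

test_that("a strongly prognostic pair is flagged candidate; a null pair has HR near 1", {
  hits <- 0
  for (seed in 1:20) {
    sim <- simulate_cohort(n_samples = 200, n_genes = 8, n_signal_pairs = 1,
                           beta = 1, seed = seed)
    prof <- build_pair_matrix(sim$expression, rownames(sim$expression))
    res <- univariate_screen(prof, sim$clinical)
    if (res$candidate[res$pair_id == sim$truth$pair_id]) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% of 20 seeds

  withr::with_seed(42, {
    n <- 1000
    surv <- make_null_surv(n)
    x <- rbinom(n, 1, 0.5)
    prof <- as_pair_profile(matrix(x, 1, dimnames = list(NULL, surv$sample)),
                            "A", "B")
    res <- univariate_screen(prof, surv)
    expect_gt(res$hr, 0.8)
    expect_lt(res$hr, 1.25)
  })
})

test_that("constant pairs are flagged inestimable, not fatal", {
  surv <- data.frame(sample = paste0("S", 1:6), time = c(1, 2, 3, 4, 5, 6),
                     event = 1L)
  v <- rbind(rep(1L, 6), c(1L, 0L, 1L, 0L, 1L, 0L))
  colnames(v) <- surv$sample
  prof <- as_pair_profile(v, c("A", "C"), c("B", "D"))
  res <- univariate_screen(prof, surv)
  expect_false(res$estimable[1])
  expect_false(res$candidate[1])
  expect_true(res$estimable[2])
})

test_that("lasso at lambda ~ 0 matches the unpenalized Cox fit; huge lambda errors", {
  sim <- simulate_cohort(n_samples = 300, n_genes = 10, n_signal_pairs = 5,
                         beta = c(0.8, -0.8), seed = 21)
  prof <- subset_pairs(build_pair_matrix(sim$expression,
                                         rownames(sim$expression)),
                       sim$truth$pair_id)
  unpen <- fit_cox(
    cbind(sim$clinical[c("time", "event")],
          as.data.frame(t(prof$values[, sim$clinical$sample]))),
    prof$pairs$pair_id
  )
  # a single near-zero penalty reduces to the unpenalized fit
  expect_warning(
    sig0 <- fit_lasso_cox(prof, sim$clinical, seed = 21, lambda_grid = 1e-6),
    "single-value lambda grid"
  )
  b <- sig0$pairs$coefficient[match(unpen$term, sig0$pairs$pair_id)]
  expect_equal(b, unpen$coef, tolerance = 1e-4)

  expect_error(
    suppressWarnings(fit_lasso_cox(prof, sim$clinical, seed = 21,
                                   lambda_grid = 1e3)),
    "empty signature"
  )
})

test_that("nonzero-coefficient count is non-increasing in lambda along the path", {
  sim <- simulate_cohort(n_samples = 300, n_genes = 12, n_signal_pairs = 4,
                         beta = c(0.8, -0.8), seed = 22)
  prof <- filter_pairs(build_pair_matrix(sim$expression,
                                         rownames(sim$expression)))
  scr <- univariate_screen(prof, sim$clinical)
  sig <- fit_lasso_cox(subset_pairs(prof, scr$pair_id[scr$candidate]),
                       sim$clinical, seed = 22)
  path <- attr(sig, "nonzero_path")  # ordered by decreasing lambda
  expect_true(all(diff(path) >= 0))
  # screen/fit consistency: every fitted pair was a screened candidate
  expect_true(all(sig$pairs$pair_id %in% scr$pair_id[scr$candidate]))
})

test_that("fold assignment is deterministic in the seed and stratified by event", {
  ev <- rep(c(0L, 1L), c(40, 60))
  f1 <- irgpair:::make_foldid(ev, 10, 7)
  f2 <- irgpair:::make_foldid(ev, 10, 7)
  f3 <- irgpair:::make_foldid(ev, 10, 8)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_equal(as.integer(table(f1[ev == 1])), rep(6L, 10))
})

test_that("scores are the linear form: zero profile, additivity, single-flip increments", {
  sig <- irgp_signature(c("A", "C", "E"), c("B", "D", "F"),
                        c(0.5, -0.25, 1), cutoff = 0)
  zero <- matrix(0L, 3, 2, dimnames = list(NULL, c("S1", "S2")))
  prof0 <- as_pair_profile(zero, sig$pairs$gene_a, sig$pairs$gene_b)
  expect_equal(unname(score_samples(sig, prof0)), c(0, 0))

  # disjoint-support additivity and per-pair increments
  m1 <- zero; m1[1, 1] <- 1L
  m2 <- zero; m2[2, 1] <- 1L
  m12 <- zero; m12[c(1, 2), 1] <- 1L
  s <- function(m) score_samples(sig, as_pair_profile(m, sig$pairs$gene_a,
                                                      sig$pairs$gene_b))[["S1"]]
  expect_equal(s(m12), s(m1) + s(m2))
  expect_equal(s(m1) - s(zero), sig$pairs$coefficient[1])
  expect_equal(s(m2) - s(zero), sig$pairs$coefficient[2])
})

test_that("scoring from raw expression builds indicators on the fly and names missing genes", {
  sig <- irgp_signature("A", "B", 2, cutoff = 1)
  expr <- matrix(c(5, 3, 1, 4), nrow = 2,
                 dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_equal(unname(score_samples(sig, expr)), c(2, 0))
  expr_bad <- matrix(1:2, 2, 1, dimnames = list(c("A", "X"), "S1"))
  expect_error(score_samples(sig, expr_bad), "B")
})

test_that("classification is strict at the cutoff and identity on empty input", {
  expect_equal(as.character(classify_samples(c(0.60, 0.538, 0.50), 0.538)),
               c("high", "low", "low"))
  expect_equal(length(classify_samples(numeric(0), 0.5)), 0)
  expect_error(classify_samples(1, NA), "finite")
})

test_that("signature JSON round-trips exactly and the schema is validated", {
  sig <- irgp_signature(c("A", "C"), c("B", "D"), c(0.123456789012, -1.5),
                        cutoff = 0.75, lambda = 0.03, provenance = "toy")
  path <- withr::local_tempfile(fileext = ".json")
  save_signature(sig, path)
  expect_equal(load_signature(path), sig)

  expect_error(irgp_signature(c("A", "A"), c("B", "B"), c(1, 2)), "duplicate")
  expect_error(irgp_signature(c("A", "B"), c("B", "A"), c(1, 2)), "duplicate")
  expect_error(irgp_signature("A", "B", NaN), "finite")
  expect_error(irgp_signature(character(0), character(0), numeric(0)),
               "at least one pair")

  # pairs/coefficients length mismatch in a hand-written file
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"pairs": [{"gene_a": "A", "gene_b": "B"}], "cutoff": 0}', bad)
  expect_error(load_signature(bad), "coefficient")
})
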
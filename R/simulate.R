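# Synthetic cohorts with the statistical structure the analysis assumes:
# log-normal expression, proportional-hazards survival driven by gene-pair
# orientation indicators, independent uniform censoring calibrated to a
# target censoring fraction, and per-sample mutation counts whose correlation
# with the true risk is controllable.

#' Simulate an expression + survival cohort with implanted pair signals
#'
#' Gene expression is drawn log-normal with gene-specific location and scale
#' (locations uniform on 2-8 and scales on 0.5-1.5 on the log2 scale, typical
#' of bulk transcriptomics after log transformation). `n_signal_pairs`
#' gene pairs with disjoint genes and orientation frequency inside
#' `[0.3, 0.7]` (so they survive the default 20% minor-frequency filter) are
#' designated signals; survival times are exponential with hazard
#' h0 exp(sum beta_p x_p), and censoring is independent Uniform(0, c_max)
#' with c_max solved numerically for the target censoring fraction.
#'
#' @param n_samples cohort size (>= 10); default 300.
#' @param n_genes number of simulated genes; default 20.
#' @param n_signal_pairs number k of truly prognostic pairs; default 5.
#' @param beta per-pair log-hazard effects, recycled to length k; default
#'   alternating +0.8 / -0.8.
#' @param baseline_hazard exponential baseline hazard h0 per day; default
#'   1/1000 (median baseline survival ~693 days, a realistic cancer-cohort
#'   scale).
#' @param censoring target censoring fraction in [0, 1); default 0.3.
#' @param noise_scale multiplier on the per-gene expression scales; default 1.
#' @param seed integer; fixes all randomness.
#' @return list with `expression` (genes x samples matrix), `clinical`
#'   (data.frame `sample`, `time`, `event`), and `truth` (data.frame of
#'   signal pairs with their `beta`, plus attributes `eta` — each sample's
#'   linear predictor — and `c_max`).
#' @examples
#' sim <- simulate_cohort(n_samples = 50, n_genes = 8, n_signal_pairs = 2,
#'                        seed = 1)
#' head(sim$clinical)
#' @export
simulate_cohort <- function(n_samples = 300, n_genes = 20, n_signal_pairs = 5,
                            beta = c(0.8, -0.8), baseline_hazard = 1 / 1000,
                            censoring = 0.3, noise_scale = 1, seed = 1) {
  if (n_samples < 10) stopf("n_samples must be >= 10")
  if (n_signal_pairs >= n_genes * (n_genes - 1) / 2) {
    stopf("n_signal_pairs must be < n_genes*(n_genes-1)/2")
  }
  if (2 * n_signal_pairs > n_genes) {
    stopf("need n_genes >= 2*n_signal_pairs for disjoint signal pairs")
  }
  if (baseline_hazard <= 0) stopf("baseline_hazard must be > 0")
  if (censoring < 0 || censoring >= 1) stopf("censoring must lie in [0, 1)")
  if (noise_scale <= 0) stopf("noise_scale must be > 0")
  beta <- rep_len(beta, n_signal_pairs)

  with_seed(seed, {
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    samples <- sprintf("SAMPLE%04d", seq_len(n_samples))
    mu <- stats::runif(n_genes, 2, 8)
    sdv <- stats::runif(n_genes, 0.5, 1.5) * noise_scale
    logx <- matrix(stats::rnorm(n_genes * n_samples, mean = mu, sd = sdv),
                   nrow = n_genes, dimnames = list(genes, samples))
    expr <- 2^logx

    # designate k disjoint signal pairs with informative orientation
    # frequency: enumerate all qualifying pairs, then greedily pick disjoint
    # ones in random order (canonical orientation: gene_a earlier in the
    # gene list)
    all_idx <- utils::combn(n_genes, 2)
    freq <- colMeans(t(expr[all_idx[1, ], , drop = FALSE] >
                         expr[all_idx[2, ], , drop = FALSE]))
    eligible <- which(freq >= 0.3 & freq <= 0.7)
    sig_idx <- matrix(0L, 0, 2)
    used <- logical(n_genes)
    for (j in eligible[sample.int(length(eligible))]) {
      a <- all_idx[1, j]; b <- all_idx[2, j]
      if (used[a] || used[b]) next
      sig_idx <- rbind(sig_idx, c(a, b))
      used[c(a, b)] <- TRUE
      if (nrow(sig_idx) == n_signal_pairs) break
    }
    if (nrow(sig_idx) < n_signal_pairs) {
      stopf("could not find %d disjoint signal pairs with orientation frequency in [0.3, 0.7]; expression locations too spread (degenerate configuration)",
            n_signal_pairs)
    }
    gene_a <- genes[sig_idx[, 1]]
    gene_b <- genes[sig_idx[, 2]]
    x_sig <- (expr[gene_a, , drop = FALSE] > expr[gene_b, , drop = FALSE]) * 1
    eta <- as.numeric(beta %*% x_sig)

    t_event <- stats::rexp(n_samples, rate = baseline_hazard * exp(eta))
    if (censoring > 0) {
      # expected censoring fraction under C ~ U(0, cmax) given the realized
      # event times: mean over samples of P(C < T_i) = mean(pmin(T_i/cmax, 1))
      f <- function(cmax) mean(pmin(t_event / cmax, 1)) - censoring
      c_max <- stats::uniroot(f, lower = min(t_event) * 1e-6,
                              upper = max(t_event) * 1e6, tol = 1e-8)$root
      c_time <- stats::runif(n_samples, 0, c_max)
      obs_time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    } else {
      c_max <- Inf
      obs_time <- t_event
      event <- rep(1L, n_samples)
    }

    truth <- data.frame(gene_a = gene_a, gene_b = gene_b,
                        pair_id = pair_id(gene_a, gene_b), beta = beta,
                        stringsAsFactors = FALSE)
    attr(truth, "eta") <- stats::setNames(eta, samples)
    attr(truth, "c_max") <- c_max
    attr(truth, "seed") <- seed
    list(expression = expr,
         clinical = data.frame(sample = samples, time = obs_time,
                               event = event, stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Apply a per-sample strictly monotone distortion to expression values
#'
#' Each sample's column is passed through its own strictly increasing
#' function, drawn independently per sample. Within-sample gene orderings —
#' and therefore the pair profile and everything downstream — are unchanged.
#'
#' @param expr non-negative genes x samples matrix.
#' @param family one of `"identity"`, `"affine-positive"` (a x + b, a > 0),
#'   `"log1p"` (log1p(s x), s > 0), `"power"` (x^p, p > 0), or
#'   `"rank-preserving-random"` (a random strictly increasing piecewise map
#'   of each sample's observed values).
#' @param seed integer controlling the per-sample distortion parameters.
#' @return distorted matrix of identical shape and dimnames.
#' @export
apply_monotone_distortion <- function(expr,
                                      family = c("identity", "affine-positive",
                                                 "log1p", "power",
                                                 "rank-preserving-random"),
                                      seed = 1) {
  family <- match.arg(family)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (any(expr < 0)) stopf("expression values must be non-negative")
  if (family == "identity") return(expr)
  out <- expr
  with_seed(seed, {
    for (j in seq_len(ncol(expr))) {
      x <- expr[, j]
      out[, j] <- switch(
        family,
        "affine-positive" = stats::runif(1, 0.5, 3) * x + stats::runif(1, 0, 5),
        "log1p" = log1p(stats::runif(1, 0.5, 2) * x),
        "power" = x^stats::runif(1, 0.3, 2),
        "rank-preserving-random" = {
          u <- sort(unique(x))
          newv <- cumsum(stats::runif(length(u), 0.1, 1))
          newv[match(x, u)]
        }
      )
    }
  })
  out
}

#' Simulate per-sample somatic mutation records correlated with true risk
#'
#' Per-sample mutation counts are Poisson with log-mean linear in the
#' standardized true linear predictor; the slope is calibrated analytically
#' so that the count/risk correlation approximates `target_corr`
#' (b = r / sqrt(m (1 - r^2)) with the intercept adjusted so the expected
#' count stays at `mean_count`). Counts are expanded to one MAF-like record
#' per mutation with placeholder genes, coding classes and positions.
#'
#' @param truth the `truth` record of [simulate_cohort()] (carries each
#'   sample's linear predictor).
#' @param target_corr desired correlation between mutation count and the
#'   linear predictor, |target_corr| < 1; default -0.3 (higher risk, fewer
#'   mutations, as observed in bladder-cancer cohorts).
#' @param mean_count expected mutations per sample (> 0); default 5.
#' @param seed integer.
#' @return data.frame with columns `sample`, `gene`,
#'   `variant_classification`, `position`; one row per simulated mutation
#'   (samples with zero mutations contribute no rows).
#' @export
simulate_mutations <- function(truth, target_corr = -0.3, mean_count = 5,
                               seed = 1) {
  eta <- attr(truth, "eta")
  if (is.null(eta)) stopf("truth record lacks the per-sample linear predictor")
  if (abs(target_corr) >= 1) stopf("|target_corr| must be < 1")
  if (mean_count <= 0) stopf("mean_count must be > 0")
  z <- as.numeric(scale(eta))
  if (anyNA(z)) z <- rep(0, length(eta))  # constant risk: no signal to encode
  b <- target_corr / sqrt(mean_count * (1 - target_corr^2))
  a <- log(mean_count) - b^2 / 2
  with_seed(seed, {
    counts <- stats::rpois(length(eta), lambda = exp(a + b * z))
    total <- sum(counts)
    classes <- sample(maf_coding_classes(), total, replace = TRUE,
                      prob = c(60, 6, 1, 25, 3, 1, 2, 1, 0.5, 0.5))
    data.frame(
      sample = rep(names(eta), counts),
      gene = sprintf("MUTGENE%03d", sample.int(200, total, replace = TRUE)),
      variant_classification = classes,
      position = sample.int(1e8, total, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}
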
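# Association statistics linking the risk score to clinical and immune
# feature tables: Fisher 2x2, Pearson correlation, two-group rank-sum.

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities (margins fixed)
#' of every table at most as probable as the observed one. A zero row or
#' column margin carries no information and returns p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts, rows = levels of
#'   the first factor, columns = levels of the second.
#' @return list with `p_value` and `odds_ratio` (sample odds ratio, ad/bc).
#' @examples
#' fisher_exact_2x2(matrix(c(10, 2, 3, 15), 2))$p_value
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stopf("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stopf("counts must be non-negative integers")
  }
  if (sum(table) == 0) stopf("empty table")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warnf("zero margin in 2x2 table: p = 1")
    return(list(p_value = 1, odds_ratio = or))
  }
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  # relative tolerance guards against tied probabilities drifting apart in
  # floating point (same convention as the classical implementation)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1), odds_ratio = or)
}

#' Pearson product-moment correlation with t-test p-value
#'
#' p from t = r sqrt((n - 2) / (1 - r^2)) against the t distribution with
#' n - 2 degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Two-group comparison of a numeric feature
#'
#' Two-sided Wilcoxon rank-sum p-value: exact when both groups have at most
#' 10 observations and there are no ties, normal approximation with tie
#' correction (no continuity correction) otherwise.
#'
#' @param values numeric vector.
#' @param groups two-level labels aligned with `values`.
#' @return list with `p_value`, `n1`, `n2`, `exact` (logical).
#' @export
group_compare <- function(values, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2) stopf("need exactly 2 non-empty groups")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(x) == 0 || length(y) == 0) stopf("one group is empty")
  exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  list(p_value = wt$p.value, n1 = length(x), n2 = length(y), exact = exact)
}

#' Correlate a risk score with a feature table
#'
#' Convenience wrapper reporting one Pearson (r, p) pair per feature column,
#' mirroring the usual "correlation coefficient = ..., P = ..." reporting. No
#' multiple-testing correction by default; `fdr = TRUE` appends
#' Benjamini-Hochberg q-values.
#'
#' @param scores named numeric risk scores.
#' @param features data.frame with a `sample` column plus numeric feature
#'   columns (immune-cell fractions, checkpoint expression, stromal/immune
#'   scores, tumor purity, TMB, ...).
#' @param fdr add a `q_value` column (Benjamini-Hochberg)?
#' @return data.frame with `feature`, `r`, `p_value` (and optionally
#'   `q_value`).
#' @export
associate_features <- function(scores, features, fdr = FALSE) {
  if (!("sample" %in% names(features))) stopf("features must have a 'sample' column")
  common <- intersect(names(scores), features$sample)
  if (length(common) < 3) stopf("fewer than 3 samples shared between scores and features")
  s <- scores[common]
  f <- features[match(common, features$sample), setdiff(names(features), "sample"),
                drop = FALSE]
  res <- lapply(names(f), function(col) {
    pc <- pearson_corr(as.numeric(s), as.numeric(f[[col]]))
    data.frame(feature = col, r = pc$r, p_value = pc$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (fdr) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
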
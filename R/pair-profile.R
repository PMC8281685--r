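# Within-sample gene-pair binarization and the minor-frequency filter.
#
# A pair (A, B) scores 1 in a sample iff expression(A) > expression(B)
# strictly in that sample; ties and equality score 0. Because only the
# within-sample ordering enters, the profile is invariant to any per-sample
# strictly increasing transformation of the expression values.

pair_id <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "|")

#' Construct a pair profile from a binary matrix
#'
#' Low-level constructor used by [build_pair_matrix()] and by tests that need
#' explicit pair sets. Recomputes per-pair frequencies from the values.
#'
#' @param values binary matrix, pairs x samples; rownames ignored, colnames
#'   are sample IDs.
#' @param gene_a,gene_b character vectors naming the first/second gene of each
#'   row's pair.
#' @return object of class `pair_profile`: list with `pairs` (data.frame
#'   `gene_a`, `gene_b`, `pair_id`), `values` (0/1 integer matrix with pair
#'   IDs as rownames), `freq` (named per-pair fraction of samples scoring 1).
#' @export
as_pair_profile <- function(values, gene_a, gene_b) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L))) stopf("pair values must be 0/1")
  if (length(gene_a) != nrow(values) || length(gene_b) != nrow(values)) {
    stopf("gene_a/gene_b must have one entry per row of values")
  }
  if (any(gene_a == gene_b)) stopf("a gene cannot be paired with itself")
  ids <- pair_id(gene_a, gene_b)
  key <- ifelse(gene_a < gene_b, pair_id(gene_a, gene_b), pair_id(gene_b, gene_a))
  if (anyDuplicated(key)) {
    stopf("duplicate unordered pair(s): %s",
          paste(unique(ids[duplicated(key)]), collapse = ", "))
  }
  rownames(values) <- ids
  structure(
    list(pairs = data.frame(gene_a = gene_a, gene_b = gene_b, pair_id = ids,
                            stringsAsFactors = FALSE),
         values = values,
         freq = stats::setNames(rowMeans(values), ids)),
    class = "pair_profile"
  )
}

#' @export
print.pair_profile <- function(x, ...) {
  cat(sprintf("pair_profile: %d pairs x %d samples; pair frequencies in [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values),
              if (nrow(x$values)) min(x$freq) else NA,
              if (nrow(x$values)) max(x$freq) else NA))
  invisible(x)
}

#' Binarize an expression matrix into gene-pair order indicators
#'
#' Restricts the expression matrix to the supplied immune-gene list, forms
#' every unordered gene combination once (oriented so `gene_a` precedes
#' `gene_b` in the gene-list order), and scores pair p in sample s as 1 iff
#' expression(gene_a, s) > expression(gene_b, s) strictly. Equality (exact
#' float comparison, no tolerance) scores 0. For G matched genes the profile
#' has exactly G(G-1)/2 rows.
#'
#' @param expr numeric genes x samples matrix with gene symbols as rownames.
#' @param immune_genes character vector of gene symbols; order defines pair
#'   orientation.
#' @return a [as_pair_profile()] object.
#' @examples
#' expr <- matrix(c(5, 3, 1, 1, 2, 3), nrow = 3,
#'                dimnames = list(c("A", "B", "C"), c("S1", "S2")))
#' build_pair_matrix(expr, c("A", "B", "C"))$values
#' @export
build_pair_matrix <- function(expr, immune_genes) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr))) stopf("expression matrix must have gene rownames")
  genes <- immune_genes[!duplicated(immune_genes)]
  genes <- genes[genes %in% rownames(expr)]
  if (length(genes) < 2) {
    stopf("need at least 2 immune genes present in the expression matrix; matched: %s",
          if (length(genes)) paste(genes, collapse = ", ") else "none")
  }
  idx <- utils::combn(length(genes), 2)
  a <- genes[idx[1, ]]
  b <- genes[idx[2, ]]
  vals <- (expr[a, , drop = FALSE] > expr[b, , drop = FALSE]) * 1L
  colnames(vals) <- colnames(expr)
  as_pair_profile(vals, a, b)
}

#' Filter pairs by minor-orientation frequency
#'
#' Pairs whose less frequent orientation occurs in fewer than
#' `min_minor_freq` of the samples carry almost no ordering information and
#' are removed: exactly the pairs with `min_minor_freq <= freq <= 1 -
#' min_minor_freq` (bounds inclusive) are retained, in their original order.
#'
#' @param profile a [build_pair_matrix()] result.
#' @param min_minor_freq minimum minor-orientation fraction, in (0, 0.5);
#'   default 0.20.
#' @return filtered `pair_profile`; attribute `n_removed` reports the number
#'   of dropped pairs.
#' @export
filter_pairs <- function(profile, min_minor_freq = 0.20) {
  stopifnot(inherits(profile, "pair_profile"))
  if (!(min_minor_freq > 0 && min_minor_freq < 0.5)) {
    stopf("min_minor_freq must lie in (0, 0.5)")
  }
  if (nrow(profile$values) == 0) stopf("empty pair profile")
  n <- ncol(profile$values)
  k <- rowSums(profile$values)
  # compare on the count scale with a tiny tolerance so that inclusive bounds
  # (e.g. exactly 20% of samples) are not lost to float representation
  kmin <- min_minor_freq * n
  keep <- k >= kmin - 1e-9 & k <= n - kmin + 1e-9
  if (!any(keep)) stopf("no informative pairs remain after the frequency filter")
  out <- as_pair_profile(profile$values[keep, , drop = FALSE],
                         profile$pairs$gene_a[keep], profile$pairs$gene_b[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Subset a pair profile to named pairs
#'
#' @param profile a `pair_profile`.
#' @param pair_ids character vector of `"GENEA|GENEB"` identifiers; order is
#'   preserved.
#' @return the restricted `pair_profile`.
#' @export
subset_pairs <- function(profile, pair_ids) {
  stopifnot(inherits(profile, "pair_profile"))
  missing_ids <- setdiff(pair_ids, profile$pairs$pair_id)
  if (length(missing_ids)) {
    stopf("pair(s) not present in profile: %s",
          paste(missing_ids, collapse = ", "))
  }
  i <- match(pair_ids, profile$pairs$pair_id)
  as_pair_profile(profile$values[i, , drop = FALSE],
                  profile$pairs$gene_a[i], profile$pairs$gene_b[i])
}
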
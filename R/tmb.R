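# Tumor mutation burden from somatic-variant records.

#' MAF variant-classification vocabulary
#'
#' The declared vocabulary for `Variant_Classification` values, following MAF
#' conventions. `maf_coding_classes()` is the default counting set for TMB
#' (all coding variants, synonymous included); `maf_nonsynonymous_classes()`
#' is the stricter preset.
#'
#' @return character vector of class names.
#' @export
maf_classes <- function() {
  c(maf_coding_classes(),
    "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "IGR", "RNA",
    "Targeted_Region")
}

#' @rdname maf_classes
#' @export
maf_coding_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation", "Silent",
    "Splice_Site", "Translation_Start_Site", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins")
}

#' @rdname maf_classes
#' @export
maf_nonsynonymous_classes <- function() {
  setdiff(maf_coding_classes(), "Silent")
}

#' Per-sample tumor mutation burden
#'
#' Counts, per sample, the somatic-variant records whose classification is in
#' `include_classes` and divides by the interrogated exonic length in
#' megabases: TMB = count / exome_length_mb. Samples listed in `samples` but
#' absent from the mutation table get count 0.
#'
#' @param muts data.frame with columns `sample`, `gene`,
#'   `variant_classification` (and typically `position`); one row per somatic
#'   variant. See [read_maf()].
#' @param samples optional cohort roster; defaults to the samples present in
#'   `muts`.
#' @param exome_length_mb interrogated exome size in Mb (> 0); default 38, a
#'   conventional whole-exome size.
#' @param include_classes classes to count; default all coding classes
#'   including synonymous.
#' @return data.frame with `sample`, `mutation_count`, `tmb` (mutations per
#'   megabase).
#' @examples
#' muts <- data.frame(sample = "S1", gene = "TP53",
#'                    variant_classification = "Missense_Mutation",
#'                    position = 7578406)
#' compute_tmb(muts, samples = c("S1", "S2"), exome_length_mb = 38)
#' @export
compute_tmb <- function(muts, samples = NULL, exome_length_mb = 38.0,
                        include_classes = maf_coding_classes()) {
  if (exome_length_mb <= 0) stopf("exome_length_mb must be > 0")
  need <- c("sample", "variant_classification")
  if (!all(need %in% names(muts))) {
    stopf("mutation table must have columns: %s", paste(need, collapse = ", "))
  }
  unknown <- setdiff(include_classes, maf_classes())
  if (length(unknown)) {
    stopf("unknown variant class(es): %s. Known vocabulary: %s",
          paste(unknown, collapse = ", "),
          paste(maf_classes(), collapse = ", "))
  }
  if (is.null(samples)) samples <- unique(muts$sample)
  kept <- muts[muts$variant_classification %in% include_classes, , drop = FALSE]
  counts <- table(factor(kept$sample, levels = samples))
  data.frame(sample = samples,
             mutation_count = as.integer(counts),
             tmb = as.integer(counts) / exome_length_mb,
             stringsAsFactors = FALSE)
}
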
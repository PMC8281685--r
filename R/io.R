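# Readers and writers for the external formats: expression and clinical
# tables (TSV/CSV), gene lists (one symbol per line) and MAF-lite mutation
# tables.

detect_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a gene x sample expression matrix
#'
#' Reads a delimited text file with genes in rows (TCGA convention; set
#' `transpose = TRUE` for samples-in-rows files), a header of sample IDs and
#' a gene-identifier column. Cells must all be numeric and non-missing;
#' duplicate gene symbols are collapsed per `duplicate_policy`.
#'
#' @param path TSV (default) or CSV file path.
#' @param gene_id_column name of the gene-identifier column; default the
#'   first column.
#' @param duplicate_policy `"max"` (element-wise maximum, the common
#'   probe/transcript collapse; default), `"mean"`, or `"error"`.
#' @param transpose set TRUE when samples are in rows.
#' @return numeric genes x samples matrix, row/column order as in the file
#'   (first occurrence for collapsed duplicates).
#' @export
read_expression_matrix <- function(path, gene_id_column = NULL,
                                   duplicate_policy = c("max", "mean", "error"),
                                   transpose = FALSE) {
  duplicate_policy <- match.arg(duplicate_policy)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (is.null(gene_id_column)) gene_id_column <- names(df)[1]
  if (!(gene_id_column %in% names(df))) {
    stopf("gene identifier column '%s' not found in %s", gene_id_column, path)
  }
  ids <- as.character(df[[gene_id_column]])
  vals <- df[setdiff(names(df), gene_id_column)]
  for (j in names(vals)) {
    v <- vals[[j]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        stopf("non-numeric value '%s' for gene '%s', sample '%s' in %s",
              v[bad[1]], ids[bad[1]], j, path)
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx)) {
    stopf("missing value for gene '%s', sample '%s' in %s",
          ids[na_idx[1, 1]], colnames(m)[na_idx[1, 2]], path)
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    if (duplicate_policy == "error") {
      stopf("duplicate gene identifier(s): %s", paste(dups, collapse = ", "))
    }
    fun <- if (duplicate_policy == "max") max else mean
    first <- !duplicated(ids)
    collapsed <- m[first, , drop = FALSE]
    for (g in dups) {
      block <- m[ids == g, , drop = FALSE]
      collapsed[g, ] <- apply(block, 2, fun)
    }
    m <- collapsed
  }
  if (transpose) m <- t(m)
  m
}

#' Write an expression matrix as TSV at full numeric precision
#'
#' Inverse of [read_expression_matrix()]: values are rendered with 17
#' significant digits so a write/read round trip reproduces the matrix
#' exactly.
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @param gene_id_column header name for the gene column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, gene_id_column = "gene_id") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(rownames(expr),
                   formatC(expr, digits = 17, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(gene_id_column, colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical (survival) table
#'
#' One row per sample. Rows with non-positive or missing follow-up time or a
#' missing/unmappable event are dropped with a logged count. Event coding
#' other than 0/1 is translated through `event_mapping`.
#'
#' @param path TSV/CSV file path.
#' @param time_column,event_column column names for follow-up time and event
#'   status.
#' @param id_column sample-identifier column; default the first column.
#' @param event_mapping optional named vector translating labels to 0/1,
#'   e.g. `c(Dead = 1, Alive = 0)`.
#' @return data.frame with `sample`, `time` (> 0), `event` (0/1) and any
#'   remaining columns as covariates; attribute `n_dropped` counts removed
#'   rows.
#' @export
read_clinical <- function(path, time_column = "time", event_column = "event",
                          id_column = NULL, event_mapping = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (is.null(id_column)) id_column <- names(df)[1]
  for (col in c(id_column, time_column, event_column)) {
    if (!(col %in% names(df))) stopf("column '%s' not found in %s", col, path)
  }
  time <- suppressWarnings(as.numeric(df[[time_column]]))
  ev_raw <- df[[event_column]]
  if (!is.null(event_mapping)) {
    event <- unname(event_mapping[as.character(ev_raw)])
  } else {
    event <- suppressWarnings(as.numeric(ev_raw))
  }
  ok <- !is.na(time) & time > 0 & !is.na(event) & event %in% c(0, 1)
  n_dropped <- sum(!ok)
  if (n_dropped) {
    message(sprintf("read_clinical: dropped %d sample(s) with invalid time or event",
                    n_dropped))
  }
  if (!any(ok)) stopf("no usable samples in %s", path)
  covars <- setdiff(names(df), c(id_column, time_column, event_column))
  out <- data.frame(sample = as.character(df[[id_column]])[ok],
                    time = time[ok], event = as.integer(event[ok]),
                    stringsAsFactors = FALSE)
  for (col in covars) out[[col]] <- df[[col]][ok]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and duplicates are dropped; order is preserved.
#'
#' @param path text file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (!length(x)) stopf("empty gene list: %s", path)
  x[!duplicated(x)]
}

#' Read a MAF-lite somatic mutation table
#'
#' Expects the minimal MAF columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`, `Start_Position` (tab-separated, `#` comments
#' allowed) and returns them under the package's canonical names.
#'
#' @param path TSV file path.
#' @return data.frame with `sample`, `gene`, `variant_classification`,
#'   `position`.
#' @export
read_maf <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#")
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification",
            "Start_Position")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("MAF file missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (any(!nzchar(as.character(df$Tumor_Sample_Barcode)))) {
    stopf("empty Tumor_Sample_Barcode in %s", path)
  }
  data.frame(sample = as.character(df$Tumor_Sample_Barcode),
             gene = as.character(df$Hugo_Symbol),
             variant_classification = as.character(df$Variant_Classification),
             position = as.numeric(df$Start_Position),
             stringsAsFactors = FALSE)
}

#' Write a MAF-lite somatic mutation table
#'
#' @param muts data.frame as returned by [read_maf()] or
#'   [simulate_mutations()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(muts, path) {
  out <- data.frame(Tumor_Sample_Barcode = muts$sample,
                    Hugo_Symbol = muts$gene,
                    Variant_Classification = muts$variant_classification,
                    Start_Position = muts$position,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
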
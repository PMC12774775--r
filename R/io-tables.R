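NARROWPEAK_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                     "signal", "pvalue", "qvalue", "summit")

#' Read / write narrowPeak files
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signal,
#' -log10(p), -log10(q), summit offset from start. Coordinates are 0-based
#' half-open, as in the file format.
#'
#' @param path file path.
#' @return data.frame with the ten narrowPeak columns.
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) != 10L) stop("expected 10 narrowPeak columns, got ", ncol(df))
  names(df) <- NARROWPEAK_COLS
  df
}

#' @rdname read_narrowpeak
#' @param peaks narrowPeak-style data.frame.
#' @param header_comment optional `#`-prefixed header line (e.g. seed note).
#' @export
write_narrowpeak <- function(peaks, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(peaks[, NARROWPEAK_COLS], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the TSS annotation table
#'
#' BED6 plus a `tss` column: chrom, start, end (gene span, 0-based
#' half-open), gene_id, score, strand, tss (0-based TSS coordinate).
#' @param path file path.
#' @return data.frame.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) != 7L) stop("expected 7 TSS-table columns, got ", ncol(df))
  names(df) <- c("chrom", "start", "end", "gene_id", "score", "strand", "tss")
  df
}

#' @rdname read_tss_table
#' @param tss_table data.frame as returned by [simulate_tss_annotation].
#' @param header_comment optional header comment.
#' @export
write_tss_table <- function(tss_table, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(
    tss_table[, c("chrom", "start", "end", "gene_id", "score", "strand",
                  "tss")],
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' Tab-separated with a header; column names are mapped to the canonical
#' `gene_id`, `log2fc`, `pvalue`, `padj`, `base_mean`.
#' @param path file path.
#' @param col_map named character vector mapping canonical names to file
#'   column names.
#' @return data.frame with canonical columns.
#' @export
read_de_table <- function(path,
                          col_map = c(gene_id = "gene_id", log2fc = "log2fc",
                                      pvalue = "pvalue", padj = "padj",
                                      base_mean = "base_mean")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(unname(col_map), names(df))
  if (length(missing) > 0L) {
    stop("DE table missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- df[, unname(col_map)]
  names(out) <- names(col_map)
  out
}

write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
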
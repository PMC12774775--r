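#' @useDynLib raregrammar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> allowed bases
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce sequence input to an upper-case character vector
#'
#' Accepts a character vector or a [Biostrings::DNAStringSet]. Names are
#' preserved; unnamed inputs get `seq_1..seq_n` identifiers.
#' @param seqs character vector or DNAStringSet.
#' @return named upper-case character vector.
#' @keywords internal
as_sequences <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet") || methods::is(seqs, "XStringSet")) {
    out <- as.character(seqs)
  } else if (is.character(seqs)) {
    out <- seqs
  } else {
    stop("sequences must be a character vector or a DNAStringSet")
  }
  out <- toupper(out)
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    names(out) <- sprintf("seq_%d", seq_along(out))
  }
  out
}

# Encode one sequence as 0-based integers (A=0,C=1,G=2,T=3), NA for any
# ambiguity code; errors on characters outside the IUPAC alphabet.
encode_dna <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% names(IUPAC_CODES))
  if (any(bad)) {
    stop("sequence contains non-IUPAC characters: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  code <- match(chars, DNA_BASES) - 1L
  code
}

encode_dna_list <- function(seqs) lapply(as_sequences(seqs), encode_dna)

#' Fraction of G/C bases in each sequence
#' @param seqs character vector or DNAStringSet.
#' @return numeric vector of per-sequence GC fractions.
#' @export
gc_fraction <- function(seqs) {
  seqs <- as_sequences(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == 0L) return(NA_real_)
    gc <- nchar(gsub("[^GCgcSs]", "", s))
    gc / n
  }, numeric(1))
}

# log2(mean(2^x)) computed stably
log2_mean_exp2 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log2(sum(2 ^ (x - m))) - log2(length(x))
}

reverse_complement_string <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop(name, " must be a fraction in [0, 1]")
  }
  invisible(x)
}
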
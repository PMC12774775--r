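#' Scan sequences for motif hits
#'
#' Scores every window of every sequence against a log-odds matrix on the
#' forward and (optionally) reverse strand and returns windows reaching the
#' hit threshold (`hit_fraction * max_score`, default 0.7). Offsets are
#' 0-based starts on forward-strand coordinates regardless of hit strand.
#' Ambiguity codes (N etc.) contribute 0 log-odds, i.e. score as background.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet].
#' @param score_matrix a [to_log_odds] result.
#' @param config a [scan_config]; its `hit_fraction` must match the one used
#'   to build `score_matrix` (the matrix's own `hit_threshold` is used).
#' @return data.frame with columns `sequence_id`, `offset`, `strand`,
#'   `score`, ordered by sequence then offset.
#' @export
scan_motifs <- function(seqs, score_matrix, config = scan_config()) {
  stopifnot(inherits(score_matrix, "score_matrix"))
  enc <- encode_dna_list(seqs)
  fwd <- unclass(score_matrix)
  rev <- unclass(rc_score_matrix(score_matrix))
  thr <- attr(score_matrix, "hit_threshold")
  res <- lapply(seq_along(enc), function(i) {
    sc <- window_scores_cpp(enc[[i]], fwd, rev)
    if (nrow(sc) == 0L) return(NULL)
    strands <- if (config$both_strands) 1:2 else 1L
    hits <- lapply(strands, function(k) {
      idx <- which(sc[, k] >= thr)
      if (length(idx) == 0L) return(NULL)
      data.frame(sequence_id = names(enc)[i], offset = idx - 1L,
                 strand = c("+", "-")[k], score = sc[idx, k],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(sequence_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(match(out$sequence_id, names(enc)), out$offset), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' ZOOPS hit count
#'
#' Zero-or-one-occurrence-per-sequence counting: `k` is the number of
#' sequences containing at least one window (either strand, if configured)
#' at or above the hit threshold; `n` is the number of sequences.
#'
#' @inheritParams scan_motifs
#' @return named integer vector `c(k = ..., n = ...)`.
#' @export
zoops_count <- function(seqs, score_matrix, config = scan_config()) {
  stopifnot(inherits(score_matrix, "score_matrix"))
  enc <- encode_dna_list(seqs)
  if (length(enc) == 0L) return(c(k = 0L, n = 0L))
  best <- max_scores_cpp(enc, unclass(score_matrix),
                         unclass(rc_score_matrix(score_matrix)),
                         config$both_strands)
  c(k = sum(best >= attr(score_matrix, "hit_threshold")),
    n = length(enc))
}

#' Average-odds sequence scores
#'
#' Per-sequence score used by the rank-sum enrichment test: log2 of the mean
#' over all windows (both strands) of `2^(window log-odds)`.
#' @inheritParams scan_motifs
#' @return numeric vector, `-Inf` for sequences shorter than the motif.
#' @export
average_odds_scores <- function(seqs, score_matrix, config = scan_config()) {
  stopifnot(inherits(score_matrix, "score_matrix"))
  enc <- encode_dna_list(seqs)
  out <- average_odds_cpp(enc, unclass(score_matrix),
                          unclass(rc_score_matrix(score_matrix)),
                          config$both_strands)
  names(out) <- names(enc)
  out
}
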
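#' Binomial ZOOPS enrichment p-value
#'
#' Upper-tail exact binomial test of the target ZOOPS count against the
#' background ZOOPS proportion: `p = P(X >= k_t)` with
#' `X ~ Binomial(n_t, k_b / n_b)`. When the background proportion is 0 and
#' `k_t > 0` the p-value underflows; the smallest positive double is
#' returned with attribute `underflow = TRUE`.
#'
#' @param k_t,n_t target hit count and sequence count.
#' @param k_b,n_b background hit count and sequence count.
#' @return p-value in (0, 1].
#' @export
binomial_enrichment <- function(k_t, n_t, k_b, n_b) {
  if (k_t > n_t || k_b > n_b) stop("k cannot exceed n")
  if (n_t < 1 || n_b < 1) stop("n_t and n_b must be >= 1")
  p0 <- k_b / n_b
  if (p0 == 0 && k_t > 0) {
    return(structure(.Machine$double.xmin, underflow = TRUE))
  }
  if (k_t == 0) return(1)
  stats::pbinom(k_t - 1, n_t, p0, lower.tail = FALSE)
}

#' One-sided Fisher enrichment p-value
#'
#' Exact test on the 2x2 table `[[k_t, n_t - k_t], [k_b, n_b - k_b]]` with
#' alternative "target proportion greater".
#' @inheritParams binomial_enrichment
#' @return p-value in (0, 1].
#' @export
fisher_enrichment <- function(k_t, n_t, k_b, n_b) {
  if (k_t > n_t || k_b > n_b) stop("k cannot exceed n")
  if (n_t < 1 || n_b < 1) stop("n_t and n_b must be >= 1")
  tab <- matrix(c(k_t, n_t - k_t, k_b, n_b - k_b), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Rank-sum (Mann-Whitney) enrichment of average-odds scores
#'
#' Scores every sequence with [average_odds_scores] and tests whether target
#' scores are stochastically greater than background scores. Sequences
#' shorter than the motif (score `-Inf`) are excluded with a warning. Small
#' untied samples (both sides <= 20) are tested exactly; otherwise a normal
#' approximation with midranks and continuity correction is used.
#'
#' @param target_seqs,background_seqs sequence sets.
#' @param score_matrix a [to_log_odds] result.
#' @param config a [scan_config].
#' @return one-sided p-value.
#' @export
ranksum_enrichment <- function(target_seqs, background_seqs, score_matrix,
                               config = scan_config()) {
  xt <- average_odds_scores(target_seqs, score_matrix, config)
  xb <- average_odds_scores(background_seqs, score_matrix, config)
  if (any(!is.finite(xt)) || any(!is.finite(xb))) {
    warning("excluding ", sum(!is.finite(xt)) + sum(!is.finite(xb)),
            " sequence(s) shorter than the motif")
    xt <- xt[is.finite(xt)]
    xb <- xb[is.finite(xb)]
  }
  if (length(xt) == 0L || length(xb) == 0L) {
    stop("both sequence sets must be non-empty after exclusions")
  }
  ties <- anyDuplicated(c(xt, xb)) > 0L
  exact <- !ties && length(xt) <= 20L && length(xb) <= 20L
  suppressWarnings(
    stats::wilcox.test(xt, xb, alternative = "greater", exact = exact,
                       correct = TRUE)$p.value)
}

#' Train a first-order Markov background model
#'
#' Transition probabilities come from dinucleotide counts with pseudocount 1;
#' the initial distribution is the mononucleotide composition. Ambiguous
#' bases break chains (the flanking dinucleotides are skipped).
#'
#' @param seqs sequence set with total length >= 100.
#' @return list of class `markov_background` with `order`, `initial`
#'   (length-4) and `transitions` (4x4 row-stochastic).
#' @export
train_markov1 <- function(seqs) {
  seqs <- as_sequences(seqs)
  if (length(seqs) == 0L || sum(nchar(seqs)) < 100L) {
    stop("need sequences totalling at least 100 bp")
  }
  trans <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  mono <- numeric(4)
  for (s in seqs) {
    code <- encode_dna(s) + 1L
    ok <- !is.na(code)
    mono <- mono + tabulate(code[ok], 4L)
    if (length(code) >= 2L) {
      a <- code[-length(code)]
      b <- code[-1L]
      keep <- !is.na(a) & !is.na(b)
      if (any(keep)) {
        tt <- table(factor(a[keep], levels = 1:4),
                    factor(b[keep], levels = 1:4))
        trans <- trans + as.matrix(tt)
      }
    }
  }
  structure(list(order = 1L,
                 initial = mono / sum(mono),
                 transitions = trans / rowSums(trans)),
            class = "markov_background")
}

#' Sample sequences from a first-order Markov model
#'
#' @param model a [train_markov1] result.
#' @param lengths integer vector of sequence lengths to generate.
#' @param seed optional integer seed (local RNG scope).
#' @return named character vector of sequences.
#' @export
sample_markov1 <- function(model, lengths, seed = NULL) {
  stopifnot(inherits(model, "markov_background"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- length(lengths)
  maxlen <- max(lengths, 0L)
  if (n == 0L || maxlen == 0L) return(character(0))
  # vectorized across sequences: one multinomial draw per position
  states <- matrix(0L, nrow = n, ncol = maxlen)
  states[, 1] <- sample.int(4L, n, replace = TRUE, prob = model$initial)
  if (maxlen >= 2L) {
    cum <- t(apply(model$transitions, 1, cumsum))
    for (j in 2:maxlen) {
      u <- stats::runif(n)
      prev <- states[, j - 1L]
      states[, j] <- 1L + rowSums(cum[prev, , drop = FALSE] < u)
    }
  }
  out <- vapply(seq_len(n), function(i) {
    paste(DNA_BASES[states[i, seq_len(lengths[i])]], collapse = "")
  }, character(1))
  names(out) <- sprintf("bg_%d", seq_len(n))
  out
}

#' Select a GC-matched background interval subset
#'
#' Samples candidate intervals without replacement so that the selection's
#' mean GC is within `tolerance` of the target peak set's mean GC, with
#' candidate lengths matched to the target length distribution by decile
#' binning. After the initial stratified draw, greedy swaps close any
#' remaining GC gap; if the gap cannot be closed the error names it.
#'
#' @param candidate_seqs candidate interval sequences.
#' @param target_seqs target peak sequences.
#' @param tolerance maximum allowed |mean GC difference| (default 0.02).
#' @param seed optional integer seed.
#' @param n_bins number of length-quantile bins.
#' @return character vector: the selected candidate subset (named by their
#'   original identifiers).
#' @export
gc_matched_background <- function(candidate_seqs, target_seqs,
                                  tolerance = 0.02, seed = NULL,
                                  n_bins = 10L) {
  cand <- as_sequences(candidate_seqs)
  targ <- as_sequences(target_seqs)
  if (length(cand) < length(targ)) {
    stop("candidate pool smaller than target set")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  target_gc <- mean(gc_fraction(targ))
  cand_gc <- gc_fraction(cand)
  # length-quantile binning against the target length distribution
  brk <- unique(stats::quantile(nchar(targ),
                                probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(brk) < 2L) brk <- c(brk - 0.5, brk + 0.5)  # all lengths equal
  bin_of <- function(len) findInterval(len, brk, rightmost.closed = TRUE,
                                       all.inside = TRUE)
  t_bins <- bin_of(nchar(targ))
  c_bins <- bin_of(nchar(cand))
  need <- table(factor(t_bins, levels = seq_len(length(brk) - 1L)))
  sel <- integer(0)
  for (b in seq_along(need)) {
    k <- as.integer(need[b])
    if (k == 0L) next
    pool <- which(c_bins == b)
    if (length(pool) < k) pool <- seq_along(cand)  # fall back to full pool
    sel <- c(sel, sample(setdiff(pool, sel), k))
  }
  gap <- function(idx) mean(cand_gc[idx]) - target_gc
  # greedy swaps toward the target mean GC
  iter <- 0L
  while (abs(gap(sel)) > tolerance && iter < 5L * length(sel)) {
    g <- gap(sel)
    outside <- setdiff(seq_along(cand), sel)
    if (length(outside) == 0L) break
    drop_i <- sel[if (g > 0) which.max(cand_gc[sel]) else which.min(cand_gc[sel])]
    add_i <- outside[if (g > 0) which.min(cand_gc[outside]) else which.max(cand_gc[outside])]
    new_sel <- c(setdiff(sel, drop_i), add_i)
    if (abs(gap(new_sel)) >= abs(g)) break  # no further improvement possible
    sel <- new_sel
    iter <- iter + 1L
  }
  if (abs(gap(sel)) > tolerance) {
    stop(sprintf(
      "GC tolerance unattainable: achieved mean-GC gap %.4f > tolerance %.4f",
      abs(gap(sel)), tolerance))
  }
  cand[sort(sel)]
}

#' Repeat-type x spacer enrichment matrix
#'
#' For every repeat kind and spacer (plus the monomer half-site, always
#' included) and every labeled peak subset, computes ZOOPS counts against a
#' shared background and an enrichment p-value. Cells with
#' `-log10(p) < 1.3` are flagged not enriched (`N.E.`). For the binomial
#' method, a background ZOOPS count of zero is floored at the rule-of-three
#' style proportion `1/(n_b + 1)` so that a lone spurious target hit cannot
#' claim an unbounded significance.
#'
#' @param peak_subsets named list of sequence sets (character or
#'   DNAStringSet), one per subset label.
#' @param half_site half-site [pfm].
#' @param background_seqs shared background sequence set.
#' @param kinds repeat kinds to test.
#' @param spacers integer spacer lengths.
#' @param method `"binomial"`, `"fisher"` or `"ranksum"`.
#' @param config a [scan_config].
#' @return data.frame in long format: `subset`, `motif_label`, `kind`,
#'   `spacer`, `k_t`, `n_t`, `k_b`, `n_b`, `p_value`, `neg_log10_p`,
#'   `enriched` (logical, `-log10 p >= 1.3`).
#' @export
repeat_enrichment_matrix <- function(peak_subsets, half_site,
                                     background_seqs,
                                     kinds = c("DR", "ER", "IR"),
                                     spacers = 0:12,
                                     method = c("binomial", "fisher",
                                                "ranksum"),
                                     config = scan_config()) {
  method <- match.arg(method)
  if (!is.list(peak_subsets) || is.null(names(peak_subsets))) {
    stop("peak_subsets must be a named list of sequence sets")
  }
  stopifnot(all(kinds %in% c("DR", "ER", "IR")))
  bg <- as_sequences(background_seqs)
  for (subset in names(peak_subsets)) {
    if (length(peak_subsets[[subset]]) == 0L) {
      warning("empty subset '", subset, "': reporting p = 1")
    }
  }
  motifs <- list(monomer = half_site)
  for (k in kinds) {
    for (s in spacers) {
      rm <- build_repeat(half_site, k, s, background = config$background)
      motifs[[rm$label]] <- rm$composite
    }
  }
  rows <- list()
  for (label in names(motifs)) {
    m <- motifs[[label]]
    sm <- to_log_odds(m, config)
    kb <- zoops_count(bg, sm, config)
    kind <- if (label == "monomer") NA_character_ else substr(label, 1, 2)
    spacer <- if (label == "monomer") NA_integer_ else
      as.integer(substring(label, 3))
    for (subset in names(peak_subsets)) {
      seqs <- as_sequences(peak_subsets[[subset]])
      if (length(seqs) == 0L) {
        kt <- c(k = 0L, n = 0L)
        p <- 1
      } else {
        kt <- zoops_count(seqs, sm, config)
        p <- switch(method,
          # zero background ZOOPS hits give a degenerate p0 = 0; floor the
          # background proportion at 1/(n_b + 1) (rule-of-three style) so a
          # single spurious target hit cannot dominate the matrix
          binomial = if (kb["k"] == 0L && kt["k"] > 0L) {
            stats::pbinom(kt["k"] - 1, kt["n"], 1 / (kb["n"] + 1),
                          lower.tail = FALSE)
          } else {
            binomial_enrichment(kt["k"], kt["n"], kb["k"], kb["n"])
          },
          fisher = fisher_enrichment(kt["k"], kt["n"], kb["k"], kb["n"]),
          ranksum = ranksum_enrichment(seqs, bg, sm, config))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subset = subset, motif_label = label, kind = kind, spacer = spacer,
        k_t = unname(kt["k"]), n_t = unname(kt["n"]),
        k_b = unname(kb["k"]), n_b = unname(kb["n"]),
        p_value = as.numeric(p), neg_log10_p = -log10(as.numeric(p)),
        enriched = -log10(as.numeric(p)) >= 1.3,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
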
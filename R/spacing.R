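#' Spacing analysis configuration
#'
#' @param margin bp retained on each side of the primary site.
#' @param min_overlap_exclusion secondary placements overlapping the primary
#'   site by at least this many bp are excluded.
#' @param pseudocount log-odds pseudocount.
#' @param secondary_min_fraction fraction of the secondary motif's maximum
#'   log-odds a site must reach to qualify.
#' @param report_cutoff p-value threshold for reported spacings.
#' @param bin_size gap histogram bin width in bp.
#' @return list of class `spacing_config`.
#' @export
spacing_config <- function(margin = 100L, min_overlap_exclusion = 6L,
                           pseudocount = 1e-4,
                           secondary_min_fraction = 0.75,
                           report_cutoff = 1e-5, bin_size = 1L) {
  if (!(secondary_min_fraction > 0 && secondary_min_fraction <= 1)) {
    stop("secondary_min_fraction must be in (0, 1]")
  }
  if (margin < 1) stop("margin must be positive")
  structure(list(margin = as.integer(margin),
                 min_overlap_exclusion = as.integer(min_overlap_exclusion),
                 pseudocount = pseudocount,
                 secondary_min_fraction = secondary_min_fraction,
                 report_cutoff = report_cutoff,
                 bin_size = as.integer(bin_size)),
            class = "spacing_config")
}

#' Center and orient sequences on their best primary motif site
#'
#' Finds the best primary site per sequence (hit threshold 0.7 x maximum
#' log-odds), trims to the site plus `margin` bp on each side (clipped at
#' sequence ends), and re-orients so the primary site reads 5'->3' on the
#' forward strand. Sequences without a qualifying primary site are dropped.
#'
#' @param seqs sequence set.
#' @param primary_sm [to_log_odds] matrix of the primary motif.
#' @param margin bp kept on each side of the primary site.
#' @param config a [scan_config] (controls the primary hit fraction).
#' @return list with `windows` (named character vector of oriented windows),
#'   `primary_offset` (0-based start of the primary site inside each
#'   window), `primary_width`, and `n_dropped`.
#' @export
center_on_primary <- function(seqs, primary_sm, margin = 100L,
                              config = scan_config()) {
  stopifnot(inherits(primary_sm, "score_matrix"))
  seqs <- as_sequences(seqs)
  w <- ncol(primary_sm)
  thr <- attr(primary_sm, "hit_threshold")
  enc <- encode_dna_list(seqs)
  fwd <- unclass(primary_sm)
  rev <- unclass(rc_score_matrix(primary_sm))
  windows <- character(0)
  offsets <- integer(0)
  n_dropped <- 0L
  for (i in seq_along(enc)) {
    sc <- window_scores_cpp(enc[[i]], fwd, rev)
    if (nrow(sc) == 0L || max(sc) < thr) {
      n_dropped <- n_dropped + 1L
      next
    }
    best <- arrayInd(which.max(sc), dim(sc))
    start0 <- best[1] - 1L          # 0-based primary start on forward coords
    strand <- c("+", "-")[best[2]]
    len <- nchar(seqs[i])
    lo <- max(0L, start0 - margin)
    hi <- min(len, start0 + w + margin)
    win <- substr(seqs[i], lo + 1L, hi)
    off <- start0 - lo              # primary offset inside window, forward
    if (strand == "-") {
      win <- reverse_complement_string(win)
      off <- nchar(win) - off - w   # offset after reverse complementing
    }
    windows <- c(windows, stats::setNames(win, names(seqs)[i]))
    offsets <- c(offsets, off)
  }
  list(windows = windows, primary_offset = offsets, primary_width = w,
       n_dropped = n_dropped)
}

#' Gap x quadrant histogram of best secondary sites
#'
#' For each centered window, the single best secondary site with score at
#' least `secondary_min_fraction` x maximum log-odds, non-negative
#' edge-to-edge gap from the primary site (placements overlapping the
#' primary by >= `min_overlap_exclusion` bp are excluded; smaller overlaps
#' count as gap 0) is assigned to one (gap, quadrant) cell. Quadrants are
#' relative to the oriented primary site: same/opposite strand x
#' downstream (3') / upstream (5').
#'
#' @param centered a [center_on_primary] result.
#' @param secondary_sm [to_log_odds] matrix of the secondary motif.
#' @param config a [spacing_config].
#' @return list with `counts` (data.frame `gap`, `quadrant`, `count`),
#'   `n_effective`, `n_without_secondary`.
#' @export
spacing_histogram <- function(centered, secondary_sm,
                              config = spacing_config()) {
  stopifnot(inherits(secondary_sm, "score_matrix"))
  ws <- ncol(secondary_sm)
  if (ws > config$margin) stop("secondary motif wider than margin")
  thr <- config$secondary_min_fraction * attr(secondary_sm, "max_score")
  fwd <- unclass(secondary_sm)
  rev <- unclass(rc_score_matrix(secondary_sm))
  wp <- centered$primary_width
  cells <- list()
  n_eff <- 0L
  n_without <- 0L
  quadrants <- c("same_strand_downstream", "same_strand_upstream",
                 "opposite_downstream", "opposite_upstream")
  for (i in seq_along(centered$windows)) {
    enc <- encode_dna(centered$windows[[i]])
    sc <- window_scores_cpp(enc, fwd, rev)
    if (nrow(sc) == 0L) { n_without <- n_without + 1L; next }
    p_start <- centered$primary_offset[i]
    p_end <- p_start + wp            # 0-based half-open primary interval
    starts <- seq_len(nrow(sc)) - 1L
    ends <- starts + ws
    overlap <- pmax(0L, pmin(ends, p_end) - pmax(starts, p_start))
    gap_raw <- ifelse(starts >= p_end, starts - p_end,
                      ifelse(ends <= p_start, p_start - ends, 0L))
    ok_pos <- overlap < config$min_overlap_exclusion
    cand <- which(ok_pos)
    if (length(cand) == 0L) { n_without <- n_without + 1L; next }
    qual <- cand[sc[cand, 1] >= thr | sc[cand, 2] >= thr]
    if (length(qual) == 0L) { n_without <- n_without + 1L; next }
    best_sc <- apply(sc[qual, , drop = FALSE], 1, max)
    j <- qual[which.max(best_sc)]
    same <- sc[j, 1] >= sc[j, 2]
    s0 <- j - 1L
    e0 <- s0 + ws
    # side relative to the primary site; partial overlaps (< exclusion) are
    # sided by motif centers
    down <- if (s0 >= p_end) TRUE else if (e0 <= p_start) FALSE else
      (s0 + e0) / 2 >= (p_start + p_end) / 2
    q <- if (same && down) quadrants[1] else if (same) quadrants[2]
         else if (down) quadrants[3] else quadrants[4]
    g <- gap_raw[j] %/% config$bin_size * config$bin_size
    n_eff <- n_eff + 1L
    key <- paste(g, q, sep = "|")
    cells[[key]] <- (cells[[key]] %||% 0L) + 1L
  }
  counts <- if (length(cells) == 0L) {
    data.frame(gap = integer(), quadrant = character(), count = integer(),
               stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(names(cells), "|", fixed = TRUE)
    data.frame(gap = as.integer(vapply(parts, `[`, "", 1)),
               quadrant = vapply(parts, `[`, "", 2),
               count = unlist(cells, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  counts <- counts[order(counts$gap, counts$quadrant), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, n_effective = n_eff, n_without_secondary = n_without,
       secondary_width = ws)
}

#' Binomial significance of spacing cells
#'
#' Each (gap, quadrant) cell is tested against a uniform null: with `G`
#' admissible gap bins (`G = floor((margin - secondary_width) / bin_size) + 1`)
#' and 4 quadrants, the null cell probability is `1 / (4 G)`. The E-value
#' multiplies the binomial upper-tail p-value by the `4 G` cells tested and
#' by the number of secondary motifs in the database.
#'
#' @param histogram a [spacing_histogram] result.
#' @param n_secondary_motifs number of secondary motifs scanned.
#' @param config a [spacing_config].
#' @param primary_label,secondary_label labels carried into the output.
#' @return data.frame of spacings with `p_value < report_cutoff`, sorted by
#'   `e_value`: columns `primary`, `secondary`, `gap`, `quadrant`, `count`,
#'   `n_effective`, `p_value`, `e_value`.
#' @export
spacing_significance <- function(histogram, n_secondary_motifs = 1L,
                                 config = spacing_config(),
                                 primary_label = "primary",
                                 secondary_label = "secondary") {
  n_eff <- histogram$n_effective
  if (n_eff < 1L) stop("n_effective must be >= 1")
  G <- (config$margin - histogram$secondary_width) %/% config$bin_size + 1L
  if (G <= 0L) stop("no admissible gap bins: margin too small for motif")
  p0 <- 1 / (4 * G)
  h <- histogram$counts
  p <- vapply(h$count, function(k) {
    stats::pbinom(k - 1, n_eff, p0, lower.tail = FALSE)
  }, numeric(1))
  out <- data.frame(primary = primary_label, secondary = secondary_label,
                    gap = h$gap, quadrant = h$quadrant, count = h$count,
                    n_effective = n_eff, p_value = p,
                    e_value = pmin(p * 4 * G * n_secondary_motifs, Inf),
                    stringsAsFactors = FALSE)
  out <- out[out$p_value < config$report_cutoff, , drop = FALSE]
  out <- out[order(out$e_value, out$gap), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end spacing co-occurrence analysis
#'
#' Convenience wrapper: centers sequences on the primary motif, builds the
#' gap histogram for each secondary motif and reports significant spacings
#' with E-values adjusted for the number of secondary motifs.
#'
#' @param seqs sequence set (e.g. peak sequences).
#' @param primary primary motif ([pfm] or [build_repeat] result).
#' @param secondaries named list of secondary [pfm]s.
#' @param config a [spacing_config].
#' @param scan_cfg a [scan_config] for the primary hit threshold.
#' @return data.frame of significant spacings across all secondaries.
#' @export
run_spacing <- function(seqs, primary, secondaries,
                        config = spacing_config(),
                        scan_cfg = scan_config(pseudocount = config$pseudocount)) {
  if (inherits(secondaries, "pfm")) secondaries <- list(secondary = secondaries)
  psm <- to_log_odds(primary, scan_cfg)
  centered <- center_on_primary(seqs, psm, margin = config$margin,
                                config = scan_cfg)
  res <- lapply(names(secondaries), function(nm) {
    ssm <- to_log_odds(secondaries[[nm]], scan_cfg)
    hist <- spacing_histogram(centered, ssm, config)
    if (hist$n_effective < 1L) return(NULL)
    spacing_significance(hist, n_secondary_motifs = length(secondaries),
                         config = config,
                         primary_label = attr(unclass(psm), "name") %||% "primary",
                         secondary_label = nm)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(primary = character(), secondary = character(),
                      gap = integer(), quadrant = character(),
                      count = integer(), n_effective = integer(),
                      p_value = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$e_value), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
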
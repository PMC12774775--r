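#' Position frequency matrices and log-odds score matrices
#'
#' A `pfm` is a 4 x w numeric matrix of per-position base probabilities with
#' rows in fixed order A, C, G, T; every column sums to 1. It is the unit of
#' all motif arithmetic in this package: half-sites, gapped-repeat composites
#' and planted-motif models are all `pfm` objects.
#'
#' @param mat numeric 4 x w matrix (rows A, C, G, T), columns summing to 1.
#' @param name motif identifier.
#' @param source free-text provenance note.
#' @return object of class `pfm`.
#' @export
pfm <- function(mat, name = "motif", source = "") {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("a PFM must have exactly 4 rows (A, C, G, T)")
  if (ncol(mat) < 1L) stop("a PFM must have width >= 1")
  if (any(mat < 0)) stop("PFM entries must be non-negative")
  csums <- colSums(mat)
  if (any(abs(csums - 1) > 1e-9)) {
    stop("every PFM column must sum to 1 (max deviation ",
         format(max(abs(csums - 1))), ")")
  }
  rownames(mat) <- DNA_BASES
  colnames(mat) <- NULL
  structure(mat, class = "pfm", name = name, source = source)
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s  width %d\n", attr(x, "name"), ncol(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

motif_width <- function(x) ncol(x)

#' Build a PFM from an IUPAC consensus string
#'
#' Each consensus letter becomes a column uniform over the bases the IUPAC
#' code allows (e.g. `R` -> A/G at 0.5 each). Note that IUPAC `K` means G/T;
#' some of the nuclear-receptor literature glosses the half-site K position
#' as G/C — this function follows IUPAC strictly.
#'
#' @param iupac consensus string over IUPAC nucleotide codes.
#' @param name motif identifier.
#' @return a [pfm].
#' @examples
#' pfm_from_consensus("RGKTCA")
#' @export
pfm_from_consensus <- function(iupac, name = iupac) {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty consensus string")
  bad <- !(chars %in% names(IUPAC_CODES))
  if (any(bad)) {
    stop("non-IUPAC character(s) in consensus: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  cols <- vapply(chars, function(ch) {
    allowed <- IUPAC_CODES[[ch]]
    col <- numeric(4)
    col[match(allowed, DNA_BASES)] <- 1 / length(allowed)
    col
  }, numeric(4))
  pfm(cols, name = name, source = paste0("consensus:", iupac))
}

#' Per-column information content of a PFM (bits)
#'
#' IC of a column is `2 + sum(p * log2(p))` with `0 * log2(0) = 0`.
#' @param x a [pfm].
#' @return numeric vector, one value per column.
#' @export
information_content <- function(x) {
  apply(unclass(x), 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Trim a PFM to its most informative core
#'
#' Either slices an explicit column window, or selects the contiguous window
#' of `core_width` columns maximizing total information content (leftmost
#' window on ties).
#'
#' @param x a [pfm].
#' @param core_width target width.
#' @param window optional explicit integer range of columns to keep
#'   (overrides the IC search).
#' @return trimmed [pfm].
#' @export
trim_to_core <- function(x, core_width, window = NULL) {
  w <- motif_width(x)
  if (!is.null(window)) {
    window <- as.integer(window)
    if (min(window) < 1L || max(window) > w) stop("window out of range")
    keep <- seq(min(window), max(window))
  } else {
    core_width <- as.integer(core_width)
    if (core_width > w) stop("core_width (", core_width,
                             ") exceeds PFM width (", w, ")")
    ic <- information_content(x)
    totals <- vapply(seq_len(w - core_width + 1L),
                     function(i) sum(ic[i:(i + core_width - 1L)]),
                     numeric(1))
    i0 <- which.max(totals)  # which.max takes the leftmost tie
    keep <- i0:(i0 + core_width - 1L)
  }
  pfm(unclass(x)[, keep, drop = FALSE],
      name = paste0(attr(x, "name"), "_core"),
      source = attr(x, "source"))
}

#' Reverse complement of a PFM
#'
#' Columns are reversed and base rows swapped A<->T, C<->G. An involution:
#' `pfm_reverse_complement(pfm_reverse_complement(x))` equals `x`.
#' @param x a [pfm].
#' @return reverse-complemented [pfm].
#' @export
pfm_reverse_complement <- function(x) {
  m <- unclass(x)
  m <- m[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(m))), drop = FALSE]
  pfm(m, name = paste0(attr(x, "name"), "_rc"), source = attr(x, "source"))
}

#' Build a gapped repeat motif from a half-site
#'
#' Composes two copies of the half-site PFM around `spacer` background
#' columns. Orientation conventions (half-site arrow = its 5'->3' reading):
#' \describe{
#'   \item{DR}{direct repeat, ->N-> : `H | spacer | H`}
#'   \item{IR}{inverted repeat, head-to-head ->N<- : `H | spacer | rc(H)`}
#'   \item{ER}{everted repeat, tail-to-tail <-N-> : `rc(H) | spacer | H`}
#' }
#' Misassigning ER vs IR silently swaps their results downstream, so the
#' convention above is normative for this package. Spacer columns equal the
#' background distribution and therefore contribute exactly 0 log-odds.
#'
#' @param half half-site [pfm].
#' @param kind one of `"DR"`, `"ER"`, `"IR"`.
#' @param spacer integer gap length (default range 0-12).
#' @param background length-4 base distribution for spacer columns.
#' @param max_spacer upper bound on `spacer`.
#' @return object of class `repeat_motif` with elements `kind`, `spacer`,
#'   `half_site`, `composite` (a [pfm]) and `label` (e.g. `"DR5"`).
#' @examples
#' build_repeat(pfm_from_consensus("RGKTCA"), "DR", 5)
#' @export
build_repeat <- function(half, kind = c("DR", "ER", "IR"), spacer,
                         background = rep(0.25, 4), max_spacer = 12L) {
  kind <- match.arg(kind)
  spacer <- as.integer(spacer)
  if (spacer < 0L) stop("spacer must be non-negative")
  if (spacer > max_spacer) stop("spacer exceeds max_spacer (", max_spacer, ")")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  h <- unclass(half)
  rc <- unclass(pfm_reverse_complement(half))
  gap <- if (spacer > 0L) matrix(background, nrow = 4, ncol = spacer) else
    matrix(numeric(0), nrow = 4, ncol = 0)
  m <- switch(kind,
    DR = cbind(h, gap, h),
    IR = cbind(h, gap, rc),
    ER = cbind(rc, gap, h))
  label <- paste0(kind, spacer)
  structure(list(
    kind = kind, spacer = spacer, half_site = half,
    composite = pfm(m, name = label,
                    source = paste0("repeat:", attr(half, "name"))),
    label = label
  ), class = "repeat_motif")
}

#' @export
print.repeat_motif <- function(x, ...) {
  cat(sprintf("<repeat_motif> %s  (half width %d, composite width %d)\n",
              x$label, ncol(x$half_site), ncol(x$composite)))
  invisible(x)
}

#' Scanning configuration
#'
#' @param hit_fraction fraction of the maximum log-odds score defining a hit.
#' @param pseudocount probability added to both motif and background
#'   probabilities before taking log-odds.
#' @param background length-4 base composition (A, C, G, T).
#' @param both_strands scan both strands?
#' @return list of class `scan_config`.
#' @export
scan_config <- function(hit_fraction = 0.7, pseudocount = 1e-4,
                        background = rep(0.25, 4), both_strands = TRUE) {
  if (!(hit_fraction > 0 && hit_fraction <= 1)) {
    stop("hit_fraction must be in (0, 1]")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9) {
    stop("background must be a length-4 distribution summing to 1")
  }
  structure(list(hit_fraction = hit_fraction, pseudocount = pseudocount,
                 background = as.numeric(background),
                 both_strands = isTRUE(both_strands)),
            class = "scan_config")
}

#' Log-odds score matrix of a PFM
#'
#' `score(b, i) = log2((p_i(b) + pseudocount) / (bg(b) + pseudocount))`.
#' The attached `max_score` is the sum of column maxima and `hit_threshold`
#' is `hit_fraction * max_score`.
#'
#' @param x a [pfm] or [build_repeat] result (its composite is used).
#' @param config a [scan_config].
#' @return 4 x w matrix of class `score_matrix` with attributes
#'   `background`, `pseudocount`, `max_score`, `hit_threshold`, `name`.
#' @export
to_log_odds <- function(x, config = scan_config()) {
  if (inherits(x, "repeat_motif")) x <- x$composite
  stopifnot(inherits(x, "pfm"))
  bg <- config$background
  pc <- config$pseudocount
  if (pc == 0 && any(bg == 0)) {
    stop("background has a zero entry and pseudocount is 0")
  }
  m <- log2((unclass(x) + pc) / (bg + pc))
  max_score <- sum(apply(m, 2, max))
  structure(m, class = "score_matrix",
            background = bg, pseudocount = pc,
            max_score = max_score,
            hit_threshold = config$hit_fraction * max_score,
            name = attr(x, "name"))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %s  width %d  max %.3f  hit threshold %.3f\n",
              attr(x, "name"), ncol(x), attr(x, "max_score"),
              attr(x, "hit_threshold")))
  invisible(x)
}

# reverse-complement a score matrix (reverse columns, swap A<->T, C<->G)
rc_score_matrix <- function(sm) {
  m <- unclass(sm)[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(sm))), drop = FALSE]
  attributes(m)[c("background", "pseudocount", "max_score",
                  "hit_threshold", "name")] <-
    attributes(sm)[c("background", "pseudocount", "max_score",
                     "hit_threshold", "name")]
  class(m) <- "score_matrix"
  m
}
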
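#' Spike-in scale factors
#'
#' Single-scalar normalization from the per-sample spike-in read fraction
#' `f = spike_reads / (spike_reads + genome_reads)`. Scale factors are
#' `K / f` with `K = 1` (`reference = "unit"`) or `K = min(f)`
#' (`reference = "min_fraction"`, making the smallest-fraction sample's
#' scale exactly 1). The ratio between any two samples' scales equals the
#' inverse ratio of their spike fractions exactly, whichever reference is
#' chosen.
#'
#' @param spike_table data.frame with columns `sample_id`, `genome_reads`,
#'   `spike_reads`.
#' @param reference `"unit"` or `"min_fraction"`.
#' @return data.frame adding `fraction` and `scale_factor`.
#' @export
spike_scale_factors <- function(spike_table,
                                reference = c("unit", "min_fraction")) {
  reference <- match.arg(reference)
  stopifnot(all(c("sample_id", "genome_reads", "spike_reads") %in%
                  names(spike_table)))
  if (any(spike_table$spike_reads <= 0)) {
    bad <- spike_table$sample_id[spike_table$spike_reads <= 0]
    stop("zero spike-in reads for sample(s): ", paste(bad, collapse = ", "))
  }
  f <- spike_table$spike_reads /
    (spike_table$spike_reads + spike_table$genome_reads)
  K <- if (reference == "unit") 1 else min(f)
  out <- spike_table
  out$fraction <- f
  out$scale_factor <- K / f
  out
}

#' Classify differential regions by fold enrichment and FDR
#'
#' A region is `enriched` iff `FE > 0` and `FDR < 0.05` (knockout over
#' parental on the log2 scale), `depleted` iff `FE < 0` and `FDR < 0.05`,
#' else `ns`. Extreme subsets for motif comparison: the extreme-gain set is
#' `FE > extreme_abs_fe` with comparison set `FE < 0`; the extreme-loss set
#' is `FE < -extreme_abs_fe` with comparison `FE > 0` (all FDR-filtered).
#'
#' @param stats_table data.frame with columns `region`, `FE`, `FDR`.
#' @param fdr_max FDR cutoff (strict `<`).
#' @param extreme_abs_fe |FE| bound defining the extreme subsets.
#' @return list with `labels` (data.frame adding `label`), and the four
#'   region-id vectors `extreme_gain`, `extreme_gain_comparison`,
#'   `extreme_loss`, `extreme_loss_comparison`.
#' @export
classify_regions <- function(stats_table, fdr_max = 0.05,
                             extreme_abs_fe = 1.0) {
  stopifnot(all(c("region", "FE", "FDR") %in% names(stats_table)))
  if (any(stats_table$FDR < 0 | stats_table$FDR > 1, na.rm = TRUE)) {
    stop("FDR values must lie in [0, 1]")
  }
  sig <- !is.na(stats_table$FDR) & stats_table$FDR < fdr_max
  label <- rep("ns", nrow(stats_table))
  label[sig & stats_table$FE > 0] <- "enriched"
  label[sig & stats_table$FE < 0] <- "depleted"
  out <- stats_table
  out$label <- label
  list(
    labels = out,
    extreme_gain = out$region[sig & out$FE > extreme_abs_fe],
    extreme_gain_comparison = out$region[sig & out$FE < 0],
    extreme_loss = out$region[sig & out$FE < -extreme_abs_fe],
    extreme_loss_comparison = out$region[sig & out$FE > 0])
}

#' Promoter chromatin states and between-genotype transitions
#'
#' A gene's promoter (TSS +/- `window`) is scored for presence of the
#' active mark (H3K4me3) and the repressive mark (H3K27me3) in each
#' condition by peak overlap of at least `min_overlap` bp. States:
#' `active` (H3K4me3 only), `bivalent` (both), `repressed` (H3K27me3 only),
#' `quiescent` (neither). Transition labels between the two conditions:
#' same state = `maintained`; gaining bivalency = `bivalency_gained`;
#' leaving bivalency = `bivalency_lost`; active -> repressed =
#' `repressed_switch`; repressed/quiescent -> active = `activated`;
#' anything else = `other`.
#'
#' @param h3k4_peaks,h3k27_peaks named lists of peak data.frames
#'   (0-based half-open, columns `chrom`, `start`, `end`), one entry per
#'   condition; both lists must share condition names.
#' @param tss_table annotation with `chrom`, `gene_id`, `tss`.
#' @param window promoter half-width in bp.
#' @param min_overlap minimum overlap in bp to count a mark present.
#' @return data.frame per gene: state per condition plus `transition`
#'   (between the first and second condition).
#' @export
promoter_states <- function(h3k4_peaks, h3k27_peaks, tss_table,
                            window = 1000L, min_overlap = 1L) {
  conds <- names(h3k4_peaks)
  if (is.null(conds) || !identical(sort(conds), sort(names(h3k27_peaks)))) {
    stop("h3k4_peaks and h3k27_peaks must be named lists over the same conditions")
  }
  prom <- GenomicRanges::GRanges(
    seqnames = tss_table$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, tss_table$tss + 1L - window),
                              end = tss_table$tss + 1L + window))
  present <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0L) {
      return(rep(FALSE, length(prom)))
    }
    gr <- peaks_to_granges(peaks)
    hits <- GenomicRanges::findOverlaps(prom, gr, minoverlap = min_overlap)
    seq_along(prom) %in% S4Vectors::queryHits(hits)
  }
  state_of <- function(k4, k27) {
    ifelse(k4 & k27, "bivalent",
           ifelse(k4, "active", ifelse(k27, "repressed", "quiescent")))
  }
  states <- lapply(conds, function(cc) {
    state_of(present(h3k4_peaks[[cc]]), present(h3k27_peaks[[cc]]))
  })
  names(states) <- conds
  out <- data.frame(gene_id = tss_table$gene_id, stringsAsFactors = FALSE)
  for (cc in conds) out[[paste0("state_", cc)]] <- states[[cc]]
  if (length(conds) >= 2L) {
    a <- states[[1]]
    b <- states[[2]]
    trans <- ifelse(a == b, "maintained",
      ifelse(b == "bivalent", "bivalency_gained",
      ifelse(a == "bivalent", "bivalency_lost",
      ifelse(a == "active" & b == "repressed", "repressed_switch",
      ifelse(b == "active", "activated", "other")))))
    out$transition <- trans
  }
  out
}
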
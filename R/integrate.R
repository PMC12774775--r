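#' DEG-calling thresholds
#'
#' Defaults follow the integration analysis: adjusted p < 0.05 with
#' |log2FC| > 0.3 for agonist contrasts, |log2FC| > 1 for the genotype
#' contrast. All inequalities are strict. A stricter agonist preset
#' (padj < 0.01) is available via `preset = "strict_agonist"`.
#'
#' @param padj_max adjusted-p cutoff (strict `<`).
#' @param lfc_min |log2FC| cutoff for agonist contrasts (strict `>`).
#' @param genotype_lfc_min |log2FC| cutoff for the genotype contrast.
#' @param preset `"table"` (padj < 0.05) or `"strict_agonist"`
#'   (padj < 0.01).
#' @return list of class `deg_thresholds`.
#' @export
deg_thresholds <- function(padj_max = 0.05, lfc_min = 0.3,
                           genotype_lfc_min = 1.0,
                           preset = c("table", "strict_agonist")) {
  preset <- match.arg(preset)
  if (preset == "strict_agonist") padj_max <- 0.01
  if (padj_max <= 0 || lfc_min <= 0 || genotype_lfc_min <= 0) {
    stop("thresholds must be positive")
  }
  structure(list(padj_max = padj_max, lfc_min = lfc_min,
                 genotype_lfc_min = genotype_lfc_min),
            class = "deg_thresholds")
}

#' Peak-filtering configuration
#' @param q_min minimum `-log10(q)` for inclusion (strict `>`).
#' @param ko_overlap_fraction maximum tolerated fractional overlap with a
#'   knockout peak (overlap at or above removes the peak).
#' @param top_n keep at most this many peaks by integer score
#'   (NULL = keep all).
#' @return list of class `peak_filter_config`.
#' @export
peak_filter_config <- function(q_min = 5, ko_overlap_fraction = 0.1,
                               top_n = 2000L) {
  if (q_min <= 0) stop("q_min must be positive")
  if (!(ko_overlap_fraction > 0 && ko_overlap_fraction <= 1)) {
    stop("ko_overlap_fraction must be in (0, 1]")
  }
  structure(list(q_min = q_min, ko_overlap_fraction = ko_overlap_fraction,
                 top_n = if (is.null(top_n)) NULL else as.integer(top_n)),
            class = "peak_filter_config")
}

#' Silencing-call thresholds
#' @param silenced_max genes with mean normalized counts below this are
#'   "virtually silenced" in that genotype.
#' @param activated_min mean normalized counts above this count as expressed.
#' @return list of class `silencing_thresholds`.
#' @export
silencing_thresholds <- function(silenced_max = 10, activated_min = 50) {
  if (silenced_max >= activated_min) {
    stop("silenced_max must be below activated_min")
  }
  structure(list(silenced_max = silenced_max, activated_min = activated_min),
            class = "silencing_thresholds")
}

#' Prefilter a count matrix by minimum expression
#'
#' Keeps genes with at least `min_count` counts in at least `min_samples`
#' samples.
#'
#' @param counts numeric matrix, genes x samples (>= 3 samples).
#' @param min_count,min_samples filter rule.
#' @return filtered matrix with attribute `n_removed`.
#' @export
prefilter_counts <- function(counts, min_count = 10, min_samples = 3) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3L) stop("count matrix must have at least 3 samples")
  keep <- rowSums(counts >= min_count) >= min_samples
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Call differentially expressed genes from one contrast table
#'
#' A gene is a DEG iff `padj < padj_max` and `|log2fc| > lfc_min`, both
#' strict; records with missing `padj` are never DEGs.
#'
#' @param records data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @param thresholds a [deg_thresholds].
#' @param direction `"both"`, `"increased"` or `"reduced"`.
#' @param lfc_min override of the fold-change cutoff (e.g.
#'   `thresholds$genotype_lfc_min` for the genotype contrast).
#' @return character vector of gene ids.
#' @export
call_degs <- function(records, thresholds = deg_thresholds(),
                      direction = c("both", "increased", "reduced"),
                      lfc_min = thresholds$lfc_min) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(records)))
  ok <- !is.na(records$padj) &
    records$padj < thresholds$padj_max &
    abs(records$log2fc) > lfc_min
  ok <- ok & switch(direction,
                    both = TRUE,
                    increased = records$log2fc > 0,
                    reduced = records$log2fc < 0)
  unique(records$gene_id[ok])
}

#' Classify genes by agonist response pattern
#'
#' For each time point and direction, genes are partitioned by which
#' agonists elicited a DEG call in the parental line: `BOTH` (responsive to
#' both the selective and the pan agonist), `CD1530_ONLY`, `RA_ONLY`.
#' `ko_responds` is TRUE iff the knockout showed a same-direction DEG call
#' at the same time for at least one of the agents that triggered the
#' parental call.
#'
#' @param deg_sets nested list:
#'   `deg_sets[[time]][[genotype]][[agent]][[direction]]` is a character
#'   vector of gene ids, with `genotype` in `PAR`/`KO`, `agent` in
#'   `CD1530`/`RA`, `direction` in `increased`/`reduced`.
#' @return data.frame: `gene_id`, `time`, `agent_class`, `direction`,
#'   `ko_responds`.
#' @export
classify_response <- function(deg_sets) {
  rows <- list()
  for (time in names(deg_sets)) {
    for (direction in c("increased", "reduced")) {
      par_cd <- deg_sets[[time]][["PAR"]][["CD1530"]][[direction]] %||% character(0)
      par_ra <- deg_sets[[time]][["PAR"]][["RA"]][[direction]] %||% character(0)
      ko_cd <- deg_sets[[time]][["KO"]][["CD1530"]][[direction]] %||% character(0)
      ko_ra <- deg_sets[[time]][["KO"]][["RA"]][[direction]] %||% character(0)
      both <- intersect(par_cd, par_ra)
      cd_only <- setdiff(par_cd, par_ra)
      ra_only <- setdiff(par_ra, par_cd)
      add <- function(genes, class, triggering) {
        if (length(genes) == 0L) return(NULL)
        ko <- switch(triggering,
                     both = genes %in% ko_cd | genes %in% ko_ra,
                     cd = genes %in% ko_cd,
                     ra = genes %in% ko_ra)
        data.frame(gene_id = genes, time = time, agent_class = class,
                   direction = direction, ko_responds = ko,
                   stringsAsFactors = FALSE)
      }
      rows <- c(rows, list(add(both, "BOTH", "both"),
                           add(cd_only, "CD1530_ONLY", "cd"),
                           add(ra_only, "RA_ONLY", "ra")))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), time = character(),
                      agent_class = character(), direction = character(),
                      ko_responds = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# peaks -> GRanges (input is 0-based half-open narrowPeak-style data.frame)
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' Filter genotype-specific peaks
#'
#' Retains peaks with `-log10(q)` strictly above `q_min` whose overlap with
#' every knockout peak is below `ko_overlap_fraction` of the peak's own
#' length, then optionally keeps the `top_n` peaks by integer score
#' (ties broken by chromosome, then start). Idempotent.
#'
#' @param par_peaks,ko_peaks narrowPeak-style data.frames (0-based
#'   half-open; columns `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `signal`, `pvalue`, `qvalue`, `summit`).
#' @param config a [peak_filter_config].
#' @return filtered data.frame.
#' @export
filter_par_specific_peaks <- function(par_peaks, ko_peaks,
                                      config = peak_filter_config()) {
  keep <- par_peaks$qvalue > config$q_min
  peaks <- par_peaks[keep, , drop = FALSE]
  if (nrow(peaks) > 0L && !is.null(ko_peaks) && nrow(ko_peaks) > 0L) {
    gr_par <- peaks_to_granges(peaks)
    gr_ko <- peaks_to_granges(ko_peaks)
    hits <- GenomicRanges::findOverlaps(gr_par, gr_ko)
    if (length(hits) > 0L) {
      ov <- IRanges::width(IRanges::pintersect(
        gr_par[S4Vectors::queryHits(hits)],
        gr_ko[S4Vectors::subjectHits(hits)]))
      frac <- ov / IRanges::width(gr_par[S4Vectors::queryHits(hits)])
      bad <- unique(S4Vectors::queryHits(hits)[frac >= config$ko_overlap_fraction])
      if (length(bad) > 0L) peaks <- peaks[-bad, , drop = FALSE]
    }
  }
  if (!is.null(config$top_n) && nrow(peaks) > config$top_n) {
    ord <- order(-peaks$score, peaks$chrom, peaks$start)
    peaks <- peaks[sort(ord[seq_len(config$top_n)]), , drop = FALSE]
  }
  rownames(peaks) <- NULL
  peaks
}

#' Annotate peaks to their nearest TSS by summit distance
#'
#' Each peak is linked to the gene with the nearest TSS to the peak summit.
#' The distance is signed relative to gene strand (negative = upstream of
#' the TSS). Proximity tiers: `proximal_promoter` (|d| <= 250), `cre`
#' (|d| <= 3000), else `gene_body` if the summit lies inside the gene span,
#' else `distal`. Peaks on chromosomes absent from the annotation are
#' `distal` with a warning.
#'
#' @param peaks narrowPeak-style data.frame (0-based half-open with `summit`
#'   offset from `start`).
#' @param tss_table data.frame with columns `chrom`, `start`, `end`
#'   (gene span, 0-based half-open), `gene_id`, `strand`, `tss` (0-based
#'   coordinate).
#' @param proximal_bp,cre_bp tier boundaries (inclusive).
#' @return list with `links` (data.frame `peak_id`, `gene_id`, `distance`,
#'   `tier`) and `feature_distribution` (tier fractions).
#' @export
annotate_peaks <- function(peaks, tss_table, proximal_bp = 250,
                           cre_bp = 3000) {
  if (nrow(tss_table) == 0L) stop("empty TSS annotation")
  summit_abs <- peaks$start + peaks$summit
  tiers <- character(nrow(peaks))
  genes <- character(nrow(peaks))
  dists <- numeric(nrow(peaks))
  missing_chrom <- FALSE
  for (i in seq_len(nrow(peaks))) {
    cand <- tss_table[tss_table$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) {
      missing_chrom <- TRUE
      genes[i] <- NA_character_
      dists[i] <- NA_real_
      tiers[i] <- "distal"
      next
    }
    d <- summit_abs[i] - cand$tss
    j <- which.min(abs(d))
    genes[i] <- cand$gene_id[j]
    # signed relative to gene strand: negative = upstream of the TSS
    dists[i] <- if (cand$strand[j] == "-") -d[j] else d[j]
    ad <- abs(d[j])
    in_body <- any(summit_abs[i] >= cand$start & summit_abs[i] < cand$end)
    tiers[i] <- if (ad <= proximal_bp) "proximal_promoter"
      else if (ad <= cre_bp) "cre"
      else if (in_body) "gene_body"
      else "distal"
  }
  if (missing_chrom) {
    warning("peak(s) on chromosomes absent from the annotation: tier set to distal")
  }
  links <- data.frame(peak_id = peaks$name, gene_id = genes,
                      distance = dists, tier = tiers,
                      stringsAsFactors = FALSE)
  tier_levels <- c("proximal_promoter", "cre", "gene_body", "distal")
  dist_tab <- table(factor(tiers, levels = tier_levels)) / nrow(peaks)
  list(links = links,
       feature_distribution = data.frame(tier = tier_levels,
                                         fraction = as.numeric(dist_tab),
                                         stringsAsFactors = FALSE))
}

#' Integration matrix of response classes by peak proximity tier
#'
#' For every (time, agent class, direction, knockout-response) row, counts
#' total DEGs, DEGs with at least one linked peak, with at least one link
#' within the cis-regulatory window (tier `cre` or closer), and with at
#' least one link at the proximal promoter. Columns are nested, so every
#' row satisfies `total >= with_peaks >= with_cre >= with_proximal`.
#'
#' @param response_classes a [classify_response] result.
#' @param links peak-gene links (`links` element of [annotate_peaks]).
#' @return data.frame with the four nested count columns.
#' @export
build_tier_table <- function(response_classes, links) {
  genes_with_peak <- unique(links$gene_id)
  genes_cre <- unique(links$gene_id[links$tier %in%
                                      c("proximal_promoter", "cre")])
  genes_prox <- unique(links$gene_id[links$tier == "proximal_promoter"])
  combos <- expand.grid(
    time = unique(response_classes$time) %||% character(0),
    agent_class = c("BOTH", "CD1530_ONLY", "RA_ONLY"),
    direction = c("reduced", "increased"),
    ko_responds = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  combos <- combos[order(combos$time, combos$agent_class, combos$direction,
                         -combos$ko_responds), , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cc <- combos[i, ]
    sel <- response_classes$time == cc$time &
      response_classes$agent_class == cc$agent_class &
      response_classes$direction == cc$direction &
      response_classes$ko_responds == cc$ko_responds
    g <- unique(response_classes$gene_id[sel])
    data.frame(cc,
               total_degs = length(g),
               with_peaks = sum(g %in% genes_with_peak),
               with_cre = sum(g %in% genes_cre),
               with_proximal = sum(g %in% genes_prox),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditional silencing / activation calls
#'
#' A gene is `silenced_in_ko` iff its mean normalized count in the knockout
#' is below `silenced_max` while the parental mean is above `activated_min`;
#' `activated_in_ko` is the reverse; otherwise `neither`.
#'
#' @param par_means,ko_means named numeric vectors of mean normalized counts
#'   (same gene order/names).
#' @param thresholds a [silencing_thresholds].
#' @return data.frame `gene_id`, `par_mean`, `ko_mean`, `label`.
#' @export
silencing_calls <- function(par_means, ko_means,
                            thresholds = silencing_thresholds()) {
  stopifnot(length(par_means) == length(ko_means))
  genes <- names(par_means) %||% sprintf("gene_%d", seq_along(par_means))
  label <- rep("neither", length(par_means))
  label[ko_means < thresholds$silenced_max &
          par_means > thresholds$activated_min] <- "silenced_in_ko"
  label[par_means < thresholds$silenced_max &
          ko_means > thresholds$activated_min] <- "activated_in_ko"
  data.frame(gene_id = genes, par_mean = as.numeric(par_means),
             ko_mean = as.numeric(ko_means), label = label,
             stringsAsFactors = FALSE)
}
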
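# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Parameters of the synthetic data generator. Defaults emulate the
#' statistical structure of a nuclear-receptor binding study in a carcinoma
#' line: peak summit proximity tiers around 38% proximal-promoter and 20%
#' distal placements, ~300 bp peaks, a genotype x agonist x time expression
#' design in triplicate, and spike-in fractions of a few percent.
#'
#' @param seed integer RNG seed; every generator derives its stream from it.
#' @param n_chromosomes,chromosome_length genome shape (bp).
#' @param gc_content genome GC fraction.
#' @param n_genes,n_peaks annotation and peak-set sizes.
#' @param peak_width_mean,peak_width_sd normal peak-width model (bp).
#' @param tier_proportions named fractions over `proximal_promoter`, `cre`,
#'   `gene_body`, `distal`; must sum to 1.
#' @param plant_rate fraction of peaks receiving a planted motif.
#' @param n_replicates replicates per expression condition.
#' @param dispersion negative-binomial size parameter.
#' @param effect_log2fc planted agonist effect size (log2).
#' @param spike_fraction_range min/max spike-in read fraction.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L,
                       chromosome_length = 500000L, gc_content = 0.45,
                       n_genes = 60L, n_peaks = 300L,
                       peak_width_mean = 300, peak_width_sd = 75,
                       tier_proportions = c(proximal_promoter = 0.38,
                                            cre = 0.12, gene_body = 0.30,
                                            distal = 0.20),
                       plant_rate = 0.5, n_replicates = 3L,
                       dispersion = 10, effect_log2fc = 2,
                       spike_fraction_range = c(0.01, 0.05)) {
  if (chromosome_length <= 0 || n_chromosomes <= 0) {
    stop("chromosome dimensions must be positive")
  }
  stopifnot_prob(gc_content, "gc_content")
  stopifnot_prob(plant_rate, "plant_rate")
  req <- c("proximal_promoter", "cre", "gene_body", "distal")
  if (!all(req %in% names(tier_proportions))) {
    stop("tier_proportions must name: ", paste(req, collapse = ", "))
  }
  tier_proportions <- tier_proportions[req]
  stopifnot_prob(tier_proportions, "tier_proportions")
  if (abs(sum(tier_proportions) - 1) > 1e-9) {
    stop("tier_proportions must sum to 1")
  }
  if (chromosome_length <= 10 * peak_width_mean) {
    stop("chromosome_length must exceed 10 x peak_width_mean")
  }
  if (length(spike_fraction_range) != 2L ||
      any(spike_fraction_range <= 0) || any(spike_fraction_range >= 1) ||
      spike_fraction_range[1] > spike_fraction_range[2]) {
    stop("spike_fraction_range must be an increasing pair inside (0, 1)")
  }
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 gc_content = gc_content, n_genes = as.integer(n_genes),
                 n_peaks = as.integer(n_peaks),
                 peak_width_mean = peak_width_mean,
                 peak_width_sd = peak_width_sd,
                 tier_proportions = tier_proportions,
                 plant_rate = plant_rate,
                 n_replicates = as.integer(n_replicates),
                 dispersion = dispersion, effect_log2fc = effect_log2fc,
                 spike_fraction_range = spike_fraction_range),
            class = "sim_config")
}

#' Simulate a genome
#'
#' I.i.d. bases at the configured GC content (G and C equally likely within
#' the GC mass, likewise A/T). Deterministic under a fixed config seed.
#'
#' @param config a [sim_config].
#' @return [Biostrings::DNAStringSet], one record per chromosome
#'   (`chr1..chrN`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$gc_content
  probs <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
  with_seed(config$seed + 101L, {
    seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
      paste(sample(DNA_BASES, config$chromosome_length, replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_len(config$n_chromosomes))
    out
  })
}

#' Simulate a TSS annotation
#'
#' Places `n_genes` genes across the chromosomes with a minimum inter-TSS
#' spacing (default 5000 bp), random strands, and gene spans of 2-8 kb
#' clipped to the chromosome. TSS coordinates are 0-based; for minus-strand
#' genes the TSS is the right end of the span.
#'
#' @param config a [sim_config].
#' @param genome a [simulate_genome] result (defines chromosome lengths).
#' @param min_spacing minimum same-chromosome TSS spacing (bp).
#' @return data.frame: `chrom`, `start`, `end`, `gene_id`, `score`,
#'   `strand`, `tss`.
#' @export
simulate_tss_annotation <- function(config, genome, min_spacing = 5000L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      score = integer(), strand = character(),
                      tss = integer(), stringsAsFactors = FALSE))
  }
  chroms <- names(genome)
  lens <- Biostrings::width(genome)
  per_chrom <- tabulate(rep_len(seq_along(chroms), n), length(chroms))
  with_seed(config$seed + 202L, {
    rows <- list()
    gi <- 0L
    for (ci in seq_along(chroms)) {
      k <- per_chrom[ci]
      if (k == 0L) next
      L <- lens[ci]
      budget <- (L - 2L * min_spacing) %/% k
      if (budget < min_spacing) {
        stop("genome too short to place ", k, " genes on ", chroms[ci],
             " with ", min_spacing, " bp spacing")
      }
      for (j in seq_len(k)) {
        gi <- gi + 1L
        slot0 <- min_spacing + (j - 1L) * budget
        tss <- slot0 + sample.int(budget - min_spacing + 1L, 1L) - 1L
        strand <- sample(c("+", "-"), 1L)
        len <- sample(2000:8000, 1L)
        if (strand == "+") {
          start <- tss
          end <- min(L, tss + len)
        } else {
          end <- tss + 1L
          start <- max(0L, end - len)
        }
        rows[[gi]] <- data.frame(chrom = chroms[ci], start = start,
                                 end = end,
                                 gene_id = sprintf("gene_%04d", gi),
                                 score = 0L, strand = strand, tss = tss,
                                 stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate binding peaks realizing configured proximity tiers
#'
#' Each peak is assigned a proximity tier by the configured proportions and
#' its summit placed so that the realized summit-to-nearest-TSS distance
#' falls in that tier (rejection sampling against the full annotation).
#' Peaks carry integer scores (uniform 50-1000) and `-log10(q)` values
#' above the inclusion cutoff.
#'
#' @param config a [sim_config].
#' @param tss_table a [simulate_tss_annotation] result.
#' @param genome the genome (for chromosome lengths).
#' @param proximal_bp,cre_bp tier distance boundaries.
#' @return narrowPeak-style data.frame plus `intended_tier`.
#' @export
simulate_peaks <- function(config, tss_table, genome, proximal_bp = 250L,
                           cre_bp = 3000L) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(tss_table) == 0L) stop("cannot place peaks without genes")
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  nearest_dist <- function(chrom, pos) {
    cand <- tss_table[tss_table$chrom == chrom, , drop = FALSE]
    if (nrow(cand) == 0L) return(Inf)
    min(abs(pos - cand$tss))
  }
  in_gene_body <- function(chrom, pos) {
    cand <- tss_table[tss_table$chrom == chrom, , drop = FALSE]
    any(pos >= cand$start & pos < cand$end)
  }
  with_seed(config$seed + 303L, {
    tiers <- sample(names(config$tier_proportions), config$n_peaks,
                    replace = TRUE, prob = config$tier_proportions)
    rows <- vector("list", config$n_peaks)
    for (i in seq_len(config$n_peaks)) {
      tier <- tiers[i]
      placed <- FALSE
      for (try in 1:200) {
        if (tier %in% c("proximal_promoter", "cre")) {
          g <- tss_table[sample.int(nrow(tss_table), 1L), ]
          d <- if (tier == "proximal_promoter") {
            sample(seq(-proximal_bp, proximal_bp), 1L)
          } else {
            sign <- sample(c(-1L, 1L), 1L)
            sign * sample(seq(proximal_bp + 1L, cre_bp), 1L)
          }
          chrom <- g$chrom
          summit <- g$tss + d
        } else if (tier == "gene_body") {
          big <- tss_table[(tss_table$end - tss_table$start) > cre_bp + 500L, ,
                           drop = FALSE]
          if (nrow(big) == 0L) {
            stop("tier proportions unrealizable: no gene span exceeds ",
                 cre_bp, " bp")
          }
          g <- big[sample.int(nrow(big), 1L), ]
          span <- g$end - g$start
          off <- sample(seq(cre_bp + 1L, span - 1L), 1L)
          summit <- if (g$strand == "+") g$start + off else g$end - 1L - off
          chrom <- g$chrom
        } else {  # distal
          chrom <- sample(names(lens), 1L)
          summit <- sample.int(lens[[chrom]], 1L) - 1L
        }
        if (summit < 0L || summit >= lens[[chrom]]) next
        nd <- nearest_dist(chrom, summit)
        ok <- switch(tier,
          proximal_promoter = nd <= proximal_bp,
          cre = nd > proximal_bp && nd <= cre_bp,
          gene_body = nd > cre_bp && in_gene_body(chrom, summit),
          distal = nd > cre_bp && !in_gene_body(chrom, summit))
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) {
        stop("could not realize tier '", tier,
             "' on this genome (placement error)")
      }
      w <- max(50L, round(stats::rnorm(1, config$peak_width_mean,
                                       config$peak_width_sd)))
      start <- max(0L, summit - w %/% 2L)
      end <- min(lens[[chrom]], start + w)
      rows[[i]] <- data.frame(
        chrom = chrom, start = start, end = end,
        name = sprintf("peak_%05d", i),
        score = sample(50:1000, 1L), strand = ".",
        signal = round(stats::runif(1, 2, 20), 3),
        pvalue = round(stats::runif(1, 6, 90), 3),
        qvalue = round(stats::runif(1, 5.1, 80), 3),
        summit = summit - start, intended_tier = tier,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Plant motif instances into peak sequences
#'
#' A Bernoulli(`rate`) subset of peaks receives one motif instance sampled
#' column-wise from the motif's probability matrix, written at a position
#' uniform within +/- 50 bp of the summit (clipped so the instance stays
#' inside the peak), on a uniformly chosen strand (minus-strand instances
#' are inserted as their reverse complement).
#'
#' @param peaks peak data.frame (0-based half-open, with `summit`).
#' @param genome [Biostrings::DNAStringSet] to modify.
#' @param motif a [build_repeat] result or [pfm].
#' @param rate planting probability per peak.
#' @param seed integer seed.
#' @param summit_jitter maximum |offset| of the instance center from the
#'   summit (bp).
#' @return list with `genome` (modified) and `truth` (data.frame `peak_id`,
#'   `offset` within peak, `strand`, `repeat_kind`, `spacer`).
#' @export
plant_motifs <- function(peaks, genome, motif, rate, seed,
                         summit_jitter = 50L) {
  composite <- if (inherits(motif, "repeat_motif")) motif$composite else motif
  kind <- if (inherits(motif, "repeat_motif")) motif$kind else NA_character_
  spacer <- if (inherits(motif, "repeat_motif")) motif$spacer else NA_integer_
  w <- ncol(composite)
  if (any(peaks$end - peaks$start < w)) {
    stop("motif (width ", w, ") wider than the narrowest peak")
  }
  probs <- unclass(composite)
  with_seed(seed, {
    chosen <- which(stats::runif(nrow(peaks)) < rate)
    truth <- list()
    if (length(chosen) > 0L) {
      repl <- list()
      used <- list()  # per-chromosome occupied insertion starts
      for (i in chosen) {
        inst <- paste(DNA_BASES[vapply(seq_len(w), function(j) {
          sample.int(4L, 1L, prob = probs[, j])
        }, integer(1))], collapse = "")
        strand <- sample(c("+", "-"), 1L)
        written <- if (strand == "-") reverse_complement_string(inst) else inst
        chrom <- peaks$chrom[i]
        occupied <- used[[chrom]] %||% integer(0)
        pos <- NA_integer_
        # overlapping peaks share sequence: redraw so instances never
        # overwrite one another
        for (try in 1:50) {
          center <- peaks$start[i] + peaks$summit[i] +
            sample(seq(-summit_jitter, summit_jitter), 1L)
          cand <- center - w %/% 2L
          cand <- min(max(cand, peaks$start[i]), peaks$end[i] - w)
          if (!any(abs(occupied - cand) < w)) { pos <- cand; break }
        }
        if (is.na(pos)) {
          warning("no non-overlapping planting position in peak ",
                  peaks$name[i], "; peak skipped")
          next
        }
        used[[chrom]] <- c(occupied, pos)
        repl[[length(repl) + 1L]] <- list(chrom = chrom,
                                          at = as.integer(pos + 1L),
                                          value = written)
        truth[[length(truth) + 1L]] <- data.frame(
          peak_id = peaks$name[i], offset = pos - peaks$start[i],
          strand = strand, repeat_kind = kind, spacer = spacer,
          stringsAsFactors = FALSE)
      }
      for (chrom in unique(vapply(repl, `[[`, "", "chrom"))) {
        rr <- Filter(function(x) x$chrom == chrom, repl)
        at <- IRanges::IRanges(
          start = vapply(rr, `[[`, 1L, "at"),
          width = w)
        genome[[chrom]] <- Biostrings::replaceAt(
          genome[[chrom]], at,
          as(vapply(rr, `[[`, "", "value"), "DNAStringSet"))
      }
    }
    truth_df <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(peak_id = character(), offset = integer(),
                 strand = character(), repeat_kind = character(),
                 spacer = integer(), stringsAsFactors = FALSE)
    list(genome = genome, truth = truth_df)
  })
}

#' Extract peak sequences from a genome
#' @param peaks peak data.frame (0-based half-open).
#' @param genome [Biostrings::DNAStringSet].
#' @return named character vector of peak sequences.
#' @export
peak_sequences <- function(peaks, genome) {
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = peaks$start[i] + 1L,
                                    end = peaks$end[i]))
  }, character(1))
  names(out) <- peaks$name
  out
}

#' Randomly assign planted expression response classes
#'
#' Roughly 55% of genes are null; the rest receive a response class (time,
#' agent class, direction, knockout response) uniformly, and a handful of
#' genes are constructed as conditionally silenced or activated by genotype.
#'
#' @param config a [sim_config].
#' @param frac_null fraction of genes with no planted effect.
#' @param n_silenced,n_activated counts of genotype-silenced/-activated genes.
#' @return data.frame: `gene_id`, `time`, `agent_class`, `direction`,
#'   `ko_responds`, `silencing`.
#' @export
simulate_response_classes <- function(config, frac_null = 0.55,
                                      n_silenced = 3L, n_activated = 3L) {
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  with_seed(config$seed + 404L, {
    cls <- data.frame(gene_id = genes, time = NA_character_,
                      agent_class = "NONE", direction = NA_character_,
                      ko_responds = FALSE, silencing = "neither",
                      stringsAsFactors = FALSE)
    n_resp <- round((1 - frac_null) * config$n_genes)
    resp <- sample(seq_along(genes), n_resp)
    cls$time[resp] <- sample(c("6h", "48h"), n_resp, replace = TRUE)
    cls$agent_class[resp] <- sample(c("BOTH", "CD1530_ONLY", "RA_ONLY"),
                                    n_resp, replace = TRUE)
    cls$direction[resp] <- sample(c("increased", "reduced"), n_resp,
                                  replace = TRUE)
    cls$ko_responds[resp] <- sample(c(TRUE, FALSE), n_resp, replace = TRUE)
    silent_pool <- setdiff(seq_along(genes), resp)
    pick <- sample(silent_pool, min(n_silenced + n_activated,
                                    length(silent_pool)))
    cls$silencing[pick[seq_len(min(n_silenced, length(pick)))]] <- "silenced_in_ko"
    if (length(pick) > n_silenced) {
      cls$silencing[pick[(n_silenced + 1L):length(pick)]] <- "activated_in_ko"
    }
    cls
  })
}

# median-of-ratios size factors; geometric means over genes positive in all
# samples
estimate_size_factors <- function(counts) {
  logs <- log(counts)
  ok <- is.finite(rowSums(logs))
  if (!any(ok)) return(rep(1, ncol(counts)))
  geo <- rowMeans(logs[ok, , drop = FALSE])
  apply(logs[ok, , drop = FALSE], 2, function(x) exp(stats::median(x - geo)))
}

#' Simulate the expression experiment
#'
#' Generates negative-binomial counts for a genotype (PAR/KO) x agent
#' (vehicle/RA/CD1530) x time (6h/48h) design with `n_replicates` per
#' condition. Responding genes get their treated means multiplied by
#' `2^(+/- effect_log2fc)` in the contrasts their class prescribes;
#' genotype-silenced/-activated genes get near-zero means in one genotype.
#' Differential tables per contrast use a Welch two-sample t-test on
#' `log2(normalized count + 1)` with Benjamini-Hochberg adjustment; the
#' genotype contrast pools the vehicle samples of both time points.
#'
#' @param config a [sim_config] (`n_replicates >= 2`).
#' @param classes a [simulate_response_classes] result (generated from the
#'   config when NULL).
#' @param base_mean_log mean of the log-normal baseline expression model.
#' @return list: `counts`, `norm_counts`, `size_factors`, `samples`,
#'   `de_tables` (one per contrast, incl. `KO_vs_PAR`), `truth`.
#' @export
simulate_expression <- function(config, classes = NULL,
                                base_mean_log = log(200)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_replicates < 2L) {
    stop("n_replicates must be >= 2 for differential testing")
  }
  if (is.null(classes)) classes <- simulate_response_classes(config)
  genes <- classes$gene_id
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        agent = c("vehicle", "RA", "CD1530"),
                        time = c("6h", "48h"),
                        genotype = c("PAR", "KO"),
                        stringsAsFactors = FALSE)
  design$sample_id <- with(design, paste(genotype, agent, time,
                                         paste0("rep", replicate), sep = "_"))
  with_seed(config$seed + 505L, {
    base <- stats::rlnorm(length(genes), meanlog = base_mean_log, sdlog = 1)
    base[classes$silencing != "neither"] <-
      stats::runif(sum(classes$silencing != "neither"), 150, 400)
    mu <- matrix(base, nrow = length(genes), ncol = nrow(design))
    rownames(mu) <- genes
    colnames(mu) <- design$sample_id
    for (i in seq_along(genes)) {
      cl <- classes[i, ]
      if (cl$silencing == "silenced_in_ko") {
        mu[i, design$genotype == "KO"] <- 1
      } else if (cl$silencing == "activated_in_ko") {
        mu[i, design$genotype == "PAR"] <- 1
      }
      if (!is.na(cl$time) && cl$agent_class != "NONE") {
        agents <- switch(cl$agent_class, BOTH = c("RA", "CD1530"),
                         CD1530_ONLY = "CD1530", RA_ONLY = "RA")
        fc <- 2 ^ (ifelse(cl$direction == "increased", 1, -1) *
                     config$effect_log2fc)
        sel <- design$genotype == "PAR" & design$time == cl$time &
          design$agent %in% agents
        mu[i, sel] <- mu[i, sel] * fc
        if (cl$ko_responds) {
          sel_ko <- design$genotype == "KO" & design$time == cl$time &
            design$agent %in% agents
          mu[i, sel_ko] <- mu[i, sel_ko] * fc
        }
      }
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = config$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    sf <- estimate_size_factors(counts)
    norm <- sweep(counts, 2, sf, "/")
    welch_table <- function(treat_ids, ctrl_ids) {
      lt <- log2(norm[, treat_ids, drop = FALSE] + 1)
      lc <- log2(norm[, ctrl_ids, drop = FALSE] + 1)
      lfc <- rowMeans(lt) - rowMeans(lc)
      pv <- vapply(seq_len(nrow(lt)), function(i) {
        if (stats::sd(lt[i, ]) == 0 && stats::sd(lc[i, ]) == 0) {
          return(if (lfc[i] == 0) 1 else 0)
        }
        stats::t.test(lt[i, ], lc[i, ])$p.value
      }, numeric(1))
      data.frame(gene_id = genes, log2fc = lfc, pvalue = pv,
                 padj = stats::p.adjust(pv, "BH"),
                 base_mean = rowMeans(norm[, c(treat_ids, ctrl_ids),
                                           drop = FALSE]),
                 stringsAsFactors = FALSE)
    }
    de <- list()
    for (gt in c("PAR", "KO")) {
      for (ag in c("RA", "CD1530")) {
        for (tm in c("6h", "48h")) {
          tid <- design$sample_id[design$genotype == gt &
                                    design$agent == ag & design$time == tm]
          cid <- design$sample_id[design$genotype == gt &
                                    design$agent == "vehicle" &
                                    design$time == tm]
          de[[paste(gt, ag, tm, sep = "_")]] <- welch_table(tid, cid)
        }
      }
    }
    ko_v <- design$sample_id[design$genotype == "KO" &
                               design$agent == "vehicle"]
    par_v <- design$sample_id[design$genotype == "PAR" &
                                design$agent == "vehicle"]
    de[["KO_vs_PAR"]] <- welch_table(ko_v, par_v)
    list(counts = counts, norm_counts = norm, size_factors = sf,
         samples = design, de_tables = de, truth = classes)
  })
}

#' Simulate spike-in read counts
#'
#' Per-sample spike fractions drawn uniformly from the configured range;
#' spike reads are the rounded fraction of a fixed per-sample read total
#' (clamped so the realized fraction stays inside the range).
#'
#' @param config a [sim_config].
#' @param sample_ids sample names.
#' @param total_reads per-sample total read count.
#' @return data.frame: `sample_id`, `genome_reads`, `spike_reads`,
#'   `fraction`.
#' @export
simulate_spike_fractions <- function(config,
                                     sample_ids = sprintf("sample_%d", 1:6),
                                     total_reads = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  rng <- config$spike_fraction_range
  with_seed(config$seed + 606L, {
    f <- stats::runif(length(sample_ids), rng[1], rng[2])
    spike <- pmin(pmax(round(f * total_reads), ceiling(rng[1] * total_reads)),
                  floor(rng[2] * total_reads))
    data.frame(sample_id = sample_ids,
               genome_reads = total_reads - spike,
               spike_reads = spike,
               fraction = spike / total_reads,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete dataset with ground truth
#'
#' Runs the whole generator (genome, annotation, peaks, planted motifs,
#' expression, spike-ins) and optionally writes all artifacts plus a JSON
#' ground-truth manifest to `outdir`. Every output file carries the seed in
#' a header comment.
#'
#' @param config a [sim_config].
#' @param motif motif to plant (default a DR5 built on the RGKTCA
#'   half-site).
#' @param outdir optional output directory.
#' @return list: `genome`, `tss`, `peaks`, `peak_seqs`, `expression`,
#'   `spike`, `truth` (planted positions, response classes, silencing
#'   labels, spike fractions), and `files` when written.
#' @export
simulate_dataset <- function(config = sim_config(),
                             motif = build_repeat(
                               pfm_from_consensus("RGKTCA"), "DR", 5),
                             outdir = NULL) {
  genome <- simulate_genome(config)
  tss <- simulate_tss_annotation(config, genome)
  peaks <- simulate_peaks(config, tss, genome)
  planted <- plant_motifs(peaks, genome, motif, config$plant_rate,
                          seed = config$seed + 707L)
  genome <- planted$genome
  expr <- simulate_expression(config)
  spike <- simulate_spike_fractions(config)
  truth <- list(
    planted_motif_positions = planted$truth,
    gene_response_class = expr$truth,
    gene_silencing_label = stats::setNames(expr$truth$silencing,
                                           expr$truth$gene_id),
    true_spike_fractions = stats::setNames(spike$fraction, spike$sample_id))
  out <- list(genome = genome, tss = tss, peaks = peaks,
              peak_seqs = peak_sequences(peaks, genome),
              expression = expr, spike = spike, truth = truth,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    seed_note <- paste0("seed=", config$seed)
    files <- list(
      genome = file.path(outdir, "genome.fa"),
      tss = file.path(outdir, "tss.bed"),
      peaks = file.path(outdir, "peaks.narrowPeak"),
      counts = file.path(outdir, "counts.tsv"),
      spike = file.path(outdir, "spike.tsv"),
      truth = file.path(outdir, "ground_truth.json"))
    Biostrings::writeXStringSet(genome, files$genome)
    write_tss_table(tss, files$tss, seed_note)
    write_narrowpeak(peaks, files$peaks, seed_note)
    write_tsv(data.frame(gene_id = rownames(expr$counts), expr$counts,
                         check.names = FALSE), files$counts, seed_note)
    write_tsv(spike, files$spike, seed_note)
    for (nm in names(expr$de_tables)) {
      f <- file.path(outdir, paste0("de_", nm, ".tsv"))
      write_tsv(expr$de_tables[[nm]], f, seed_note)
      files[[paste0("de_", nm)]] <- f
    }
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$files <- files
  }
  out
}
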
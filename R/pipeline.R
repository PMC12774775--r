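#' Pipeline configuration
#'
#' Bundles all stage thresholds, stage toggles, and either input file paths
#' or a [sim_config] for self-generated data.
#'
#' @param sim a [sim_config] for synthetic input, or NULL to read files.
#' @param inputs named list of input paths (`genome`, `tss`, `peaks`,
#'   `de_dir`, `spike`) used when `sim` is NULL.
#' @param outdir output directory.
#' @param stages character vector of stages to run, in order, among
#'   `"simulate"`, `"repeats"`, `"enrich"`, `"spacing"`, `"integrate"`,
#'   `"chromatin"`.
#' @param half_site half-site [pfm] used for repeat construction.
#' @param spacers spacer range for repeat construction.
#' @param scan_cfg,spacing_cfg,deg_thr,peak_cfg,silencing_thr threshold
#'   bundles (see [scan_config], [spacing_config], [deg_thresholds],
#'   [peak_filter_config], [silencing_thresholds]).
#' @param seed global seed propagated to all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = list(),
                            outdir = tempfile("raregrammar_run_"),
                            stages = c("simulate", "repeats", "enrich",
                                       "spacing", "integrate", "chromatin"),
                            half_site = pfm_from_consensus("RGKTCA"),
                            spacers = 0:12,
                            scan_cfg = scan_config(),
                            spacing_cfg = spacing_config(),
                            deg_thr = deg_thresholds(),
                            peak_cfg = peak_filter_config(),
                            silencing_thr = silencing_thresholds(),
                            seed = if (!is.null(sim)) sim$seed else 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(sim)) {
    needed <- c("genome", "tss", "peaks")
    missing <- setdiff(needed, names(inputs))
    if (length(missing) > 0L) {
      stop("simulation disabled and no input path for: ",
           paste(missing, collapse = ", "))
    }
    for (f in unlist(inputs[needed])) {
      if (!file.exists(f)) stop("input file does not exist: ", f)
    }
  }
  structure(list(sim = sim, inputs = inputs, outdir = outdir,
                 stages = stages, half_site = half_site, spacers = spacers,
                 scan_cfg = scan_cfg, spacing_cfg = spacing_cfg,
                 deg_thr = deg_thr, peak_cfg = peak_cfg,
                 silencing_thr = silencing_thr, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order (simulate -> repeats -> enrich ->
#' spacing -> integrate -> chromatin), writing each stage's outputs under
#' the configured directory plus a JSON manifest recording input hashes,
#' seeds and thresholds. Reruns with the same config are content-identical.
#'
#' @param config a [pipeline_config].
#' @return the manifest, invisibly also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   thresholds = list(
                     hit_fraction = config$scan_cfg$hit_fraction,
                     pseudocount = config$scan_cfg$pseudocount,
                     padj_max = config$deg_thr$padj_max,
                     lfc_min = config$deg_thr$lfc_min,
                     q_min = config$peak_cfg$q_min,
                     ko_overlap_fraction = config$peak_cfg$ko_overlap_fraction,
                     spacing_margin = config$spacing_cfg$margin,
                     spacing_cutoff = config$spacing_cfg$report_cutoff),
                   stages = list())
  run_stage <- function(name, fn) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(
      list(elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3)),
      res)
    invisible(NULL)
  }
  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    ds <- simulate_dataset(config$sim, outdir = file.path(config$outdir,
                                                          "simulated"))
    state$data <- ds
    list(outputs = unlist(ds$files),
         hashes = as.list(tools::md5sum(unlist(ds$files))))
  })
  if (is.null(state$data)) {
    if (is.null(config$sim)) {
      genome <- Biostrings::readDNAStringSet(config$inputs$genome)
      names(genome) <- sub("\\s.*$", "", names(genome))
      tss <- read_tss_table(config$inputs$tss)
      peaks <- read_narrowpeak(config$inputs$peaks)
      state$data <- list(genome = genome, tss = tss, peaks = peaks,
                         peak_seqs = peak_sequences(peaks, genome))
    } else {
      state$data <- simulate_dataset(config$sim)
    }
  }

  run_stage("repeats", function() {
    reps <- list()
    for (k in c("DR", "ER", "IR")) {
      for (s in config$spacers) {
        reps[[length(reps) + 1L]] <- build_repeat(config$half_site, k, s)
      }
    }
    f <- file.path(config$outdir, "repeats.meme")
    write_motifs(reps, f, format = "meme")
    state$repeats <- reps
    list(outputs = f, n_motifs = length(reps),
         hashes = as.list(tools::md5sum(f)))
  })

  run_stage("enrich", function() {
    seqs <- state$data$peak_seqs
    model <- train_markov1(seqs)
    bg <- sample_markov1(model, nchar(seqs), seed = config$seed + 11L)
    mat <- repeat_enrichment_matrix(list(peaks = seqs), config$half_site,
                                    bg, spacers = config$spacers,
                                    config = config$scan_cfg)
    f <- file.path(config$outdir, "enrichment_matrix.tsv")
    write_tsv(mat, f, paste0("seed=", config$seed))
    state$enrichment <- mat
    list(outputs = f, hashes = as.list(tools::md5sum(f)))
  })

  run_stage("spacing", function() {
    seqs <- state$data$peak_seqs
    res <- run_spacing(seqs, config$half_site,
                       list(ap1 = pfm_from_consensus("TGASTCA")),
                       config = config$spacing_cfg,
                       scan_cfg = config$scan_cfg)
    f <- file.path(config$outdir, "spacing.tsv")
    write_tsv(res, f, paste0("seed=", config$seed))
    state$spacing <- res
    list(outputs = f, n_significant = nrow(res),
         hashes = as.list(tools::md5sum(f)))
  })

  run_stage("integrate", function() {
    dat <- state$data
    if (is.null(dat$expression)) {
      stop("integrate stage requires simulated expression data or DE inputs")
    }
    de <- dat$expression$de_tables
    deg_sets <- list()
    for (tm in c("6h", "48h")) {
      for (gt in c("PAR", "KO")) {
        for (ag in c("CD1530", "RA")) {
          tab <- de[[paste(gt, ag, tm, sep = "_")]]
          for (dir in c("increased", "reduced")) {
            deg_sets[[tm]][[gt]][[ag]][[dir]] <-
              call_degs(tab, config$deg_thr, dir)
          }
        }
      }
    }
    classes <- classify_response(deg_sets)
    ann <- annotate_peaks(dat$peaks, dat$tss)
    tier <- build_tier_table(classes, ann$links)
    norm <- dat$expression$norm_counts
    veh <- dat$expression$samples
    par_ids <- veh$sample_id[veh$genotype == "PAR" & veh$agent == "vehicle"]
    ko_ids <- veh$sample_id[veh$genotype == "KO" & veh$agent == "vehicle"]
    sil <- silencing_calls(rowMeans(norm[, par_ids, drop = FALSE]),
                           rowMeans(norm[, ko_ids, drop = FALSE]),
                           config$silencing_thr)
    f1 <- file.path(config$outdir, "tier_table.tsv")
    f2 <- file.path(config$outdir, "peak_gene_links.tsv")
    f3 <- file.path(config$outdir, "silencing_calls.tsv")
    write_tsv(tier, f1)
    write_tsv(ann$links, f2)
    write_tsv(sil, f3)
    state$tier <- tier
    state$feature_distribution <- ann$feature_distribution
    state$silencing <- sil
    list(outputs = c(f1, f2, f3), hashes = as.list(tools::md5sum(c(f1, f2, f3))))
  })

  run_stage("chromatin", function() {
    dat <- state$data
    spike <- if (!is.null(dat$spike)) dat$spike else
      read_tsv(config$inputs$spike)
    scales <- spike_scale_factors(spike[, c("sample_id", "genome_reads",
                                            "spike_reads")],
                                  reference = "min_fraction")
    f <- file.path(config$outdir, "spike_scale_factors.tsv")
    write_tsv(scales, f)
    state$spike_scales <- scales
    list(outputs = f, hashes = as.list(tools::md5sum(f)))
  })

  manifest$results <- list(
    enrichment = state$enrichment,
    spacing = state$spacing,
    tier_table = state$tier,
    feature_distribution = state$feature_distribution,
    silencing = state$silencing,
    spike_scales = state$spike_scales)
  jsonlite::write_json(manifest[c("seed", "thresholds", "stages")],
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Human-readable pipeline summary
#'
#' Renders the top enrichment cells, top spacings, the integration tier
#' table, silencing-call counts and spike scale factors as text.
#'
#' @param manifest a [run_pipeline] result.
#' @return character vector of report lines (also printed).
#' @export
pipeline_report <- function(manifest) {
  if (!is.list(manifest) || is.null(manifest$results)) {
    stop("corrupt manifest: no results element")
  }
  res <- manifest$results
  lines <- c("== pipeline report ==", paste0("seed: ", manifest$seed), "")
  if (!is.null(res$enrichment) && nrow(res$enrichment) > 0) {
    top <- res$enrichment[order(res$enrichment$p_value), ][
      seq_len(min(5, nrow(res$enrichment))), ]
    lines <- c(lines, "top enrichment cells (motif, -log10 p):",
               sprintf("  %-8s %8.2f %s", top$motif_label, top$neg_log10_p,
                       ifelse(top$enriched, "", "N.E.")), "")
  } else {
    lines <- c(lines, "enrichment: no cells", "")
  }
  if (!is.null(res$spacing) && nrow(res$spacing) > 0) {
    top <- res$spacing[seq_len(min(5, nrow(res$spacing))), ]
    lines <- c(lines, "top spacings (secondary, gap, quadrant, E):",
               sprintf("  %-10s gap=%-3d %-24s E=%.2e", top$secondary,
                       top$gap, top$quadrant, top$e_value), "")
  } else {
    lines <- c(lines, "spacing: no significant spacings", "")
  }
  if (!is.null(res$tier_table) && nrow(res$tier_table) > 0) {
    tt <- res$tier_table[res$tier_table$total_degs > 0, , drop = FALSE]
    lines <- c(lines, "integration tier table (total / peaks / CRE / proximal):",
               if (nrow(tt) > 0) {
                 sprintf("  %-4s %-12s %-9s ko=%-5s %5d %5d %5d %5d",
                         tt$time, tt$agent_class, tt$direction,
                         tt$ko_responds, tt$total_degs, tt$with_peaks,
                         tt$with_cre, tt$with_proximal)
               } else "  (all rows zero)", "")
  } else {
    lines <- c(lines, "integration: zero-count table", "")
  }
  if (!is.null(res$silencing)) {
    tab <- table(res$silencing$label)
    lines <- c(lines, "silencing calls:",
               sprintf("  %-16s %d", names(tab), as.integer(tab)), "")
  }
  if (!is.null(res$spike_scales)) {
    lines <- c(lines, "spike scale factors:",
               sprintf("  %-12s f=%.4f scale=%.3f",
                       res$spike_scales$sample_id, res$spike_scales$fraction,
                       res$spike_scales$scale_factor), "")
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
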
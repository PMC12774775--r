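cfg_small <- sim_config(seed = 11, n_genes = 20, n_peaks = 60,
                        chromosome_length = 200000L)

test_that("config invariants are enforced", {
  expect_error(sim_config(chromosome_length = 0), "positive")
  expect_error(sim_config(gc_content = 1.5), "fraction")
  expect_error(sim_config(tier_proportions = c(proximal_promoter = 0.5,
                                               cre = 0.2, gene_body = 0.2,
                                               distal = 0.2)), "sum to 1")
  expect_error(sim_config(chromosome_length = 2000, peak_width_mean = 300),
               "10 x")
  expect_error(sim_config(spike_fraction_range = c(0.5, 0.1)), "increasing")
})

test_that("genome simulation is deterministic with the configured GC", {
  g1 <- simulate_genome(cfg_small)
  g2 <- simulate_genome(cfg_small)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(length(g1), cfg_small$n_chromosomes)
  # binomial bound: for L = 200 kb the GC fraction is within 0.005 of the
  # target with overwhelming probability (6.9 sd)
  expect_lt(max(abs(gc_fraction(g1) - cfg_small$gc_content)), 0.005)
  all_gc <- simulate_genome(sim_config(seed = 2, gc_content = 1,
                                       chromosome_length = 10000L))
  expect_true(grepl("^[GC]+$", as.character(all_gc[[1]])))
})

test_that("TSS annotation respects spacing and bounds", {
  g <- simulate_genome(cfg_small)
  tss <- simulate_tss_annotation(cfg_small, g)
  expect_equal(nrow(tss), 20)
  expect_equal(anyDuplicated(tss$gene_id), 0L)
  expect_true(all(tss$tss >= 0 & tss$tss < cfg_small$chromosome_length))
  # brute-force pairwise spacing check
  for (chrom in unique(tss$chrom)) {
    pos <- sort(tss$tss[tss$chrom == chrom])
    if (length(pos) > 1) expect_true(all(diff(pos) >= 5000))
  }
  # empty annotation
  empty <- simulate_tss_annotation(sim_config(n_genes = 0), g)
  expect_equal(nrow(empty), 0)
  # too many genes for the genome
  tiny <- sim_config(n_genes = 500, chromosome_length = 50000L,
                     n_chromosomes = 1)
  expect_error(simulate_tss_annotation(tiny, simulate_genome(tiny)),
               "too short")
})

test_that("peaks realize their tiers with valid geometry", {
  g <- simulate_genome(cfg_small)
  tss <- simulate_tss_annotation(cfg_small, g)
  pk <- simulate_peaks(cfg_small, tss, g)
  expect_equal(nrow(pk), 60)
  expect_true(all(pk$start < pk$start + pk$summit))
  expect_true(all(pk$start + pk$summit < pk$end))
  expect_true(all(pk$qvalue > 5))
  # realized tier (by independent annotation) matches the intended tier
  ann <- annotate_peaks(pk, tss)
  expect_equal(ann$links$tier, pk$intended_tier)
  # all-proximal configuration puts every summit within 250 bp of a TSS
  all_prox <- sim_config(seed = 3, n_genes = 20, n_peaks = 40,
                         chromosome_length = 200000L,
                         tier_proportions = c(proximal_promoter = 1, cre = 0,
                                              gene_body = 0, distal = 0))
  gp <- simulate_genome(all_prox)
  tp <- simulate_tss_annotation(all_prox, gp)
  pp <- simulate_peaks(all_prox, tp, gp)
  d <- vapply(seq_len(nrow(pp)), function(i) {
    min(abs(pp$start[i] + pp$summit[i] - tp$tss[tp$chrom == pp$chrom[i]]))
  }, numeric(1))
  expect_true(all(d <= 250))
})

test_that("tier proportions are realized within binomial bounds", {
  # n = 1000 peaks, proximal target 0.38: 1000 draws give SE ~ 0.0153,
  # so +/- 0.04 is a 2.6-sigma band
  cfg <- sim_config(seed = 5, n_genes = 60, n_peaks = 1000,
                    chromosome_length = 500000L, n_chromosomes = 2)
  g <- simulate_genome(cfg)
  tss <- simulate_tss_annotation(cfg, g)
  pk <- simulate_peaks(cfg, tss, g)
  frac <- mean(pk$intended_tier == "proximal_promoter")
  expect_lt(abs(frac - 0.38), 0.04)
})

test_that("motif planting writes recoverable instances at the stated rate", {
  g <- simulate_genome(cfg_small)
  tss <- simulate_tss_annotation(cfg_small, g)
  pk <- simulate_peaks(cfg_small, tss, g)
  onehot <- build_repeat(pfm_from_consensus("ACGTAG"), "DR", 0)
  # rate 0 changes nothing
  p0 <- plant_motifs(pk, g, onehot, 0, seed = 1)
  expect_equal(nrow(p0$truth), 0)
  expect_identical(as.character(p0$genome), as.character(g))
  # rate 1 with a one-hot composite: consensus findable by substring search
  p1 <- plant_motifs(pk, g, onehot, 1, seed = 2)
  expect_equal(nrow(p1$truth), nrow(pk))
  seqs <- peak_sequences(pk, p1$genome)
  consensus <- "ACGTAGACGTAG"
  rc <- raregrammar:::reverse_complement_string(consensus)
  hitf <- function(i) {
    sub <- substr(seqs[[p1$truth$peak_id[i]]], p1$truth$offset[i] + 1,
                  p1$truth$offset[i] + nchar(consensus))
    if (p1$truth$strand[i] == "+") sub == consensus else sub == rc
  }
  expect_true(all(vapply(seq_len(nrow(p1$truth)), hitf, logical(1))))
  # every planted position lies inside its peak
  widths <- stats::setNames(pk$end - pk$start, pk$name)
  expect_true(all(p1$truth$offset >= 0))
  expect_true(all(p1$truth$offset + nchar(consensus) <=
                    widths[p1$truth$peak_id]))
  # planted count ~ Binomial(n, rate): [215, 285] has P > 0.999 at
  # n = 500, rate = 0.5
  cfg_many <- sim_config(seed = 13, n_genes = 40, n_peaks = 500,
                         chromosome_length = 400000L)
  gm <- simulate_genome(cfg_many)
  tm <- simulate_tss_annotation(cfg_many, gm)
  pm <- simulate_peaks(cfg_many, tm, gm)
  pl <- plant_motifs(pm, gm, onehot, 0.5, seed = 3)
  expect_gte(nrow(pl$truth), 215)
  expect_lte(nrow(pl$truth), 285)
  # motif wider than peaks errors
  wide <- build_repeat(pfm_from_consensus(strrep("A", 30)), "DR", 12)
  narrow <- pk
  narrow$end <- narrow$start + 40
  narrow$summit <- 20
  expect_error(plant_motifs(narrow, g, wide, 1, seed = 4), "wider")
})

test_that("expression simulation recovers planted effects and truth labels", {
  cfg <- sim_config(seed = 17, n_genes = 40, n_replicates = 6,
                    dispersion = 50, effect_log2fc = 3)
  ex <- simulate_expression(cfg)
  expect_equal(dim(ex$counts), c(40, 6 * 3 * 2 * 2))
  # silenced/activated construction holds in the emitted matrix
  veh <- ex$samples
  par_ids <- veh$sample_id[veh$genotype == "PAR" & veh$agent == "vehicle"]
  ko_ids <- veh$sample_id[veh$genotype == "KO" & veh$agent == "vehicle"]
  for (g in ex$truth$gene_id[ex$truth$silencing == "silenced_in_ko"]) {
    expect_lt(mean(ex$norm_counts[g, ko_ids]), 10)
    expect_gt(mean(ex$norm_counts[g, par_ids]), 50)
  }
  for (g in ex$truth$gene_id[ex$truth$silencing == "activated_in_ko"]) {
    expect_lt(mean(ex$norm_counts[g, par_ids]), 10)
    expect_gt(mean(ex$norm_counts[g, ko_ids]), 50)
  }
  # planted responders are recovered in their contrast with lfc near truth
  resp <- ex$truth[ex$truth$agent_class == "RA_ONLY" &
                     !is.na(ex$truth$time), ]
  for (i in seq_len(nrow(resp))) {
    tab <- ex$de_tables[[paste0("PAR_RA_", resp$time[i])]]
    row <- tab[tab$gene_id == resp$gene_id[i], ]
    sign <- if (resp$direction[i] == "increased") 1 else -1
    expect_lt(abs(row$log2fc - sign * 3), 1)
  }
  expect_error(simulate_expression(sim_config(n_replicates = 1)), ">= 2")
})

test_that("a null experiment yields calibrated DE p-values", {
  cfg <- sim_config(seed = 19, n_genes = 300, effect_log2fc = 0)
  classes <- simulate_response_classes(cfg, frac_null = 1, n_silenced = 0,
                                       n_activated = 0)
  ex <- simulate_expression(cfg, classes)
  tab <- ex$de_tables[["PAR_RA_6h"]]
  # raw p uniform: fraction below 0.05 within binomial bounds
  expect_lt(mean(tab$pvalue < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
  # BH-adjusted calls are at most the nominal rate in expectation
  expect_lte(mean(tab$padj < 0.05), 0.05)
})

test_that("spike fractions respect range, determinism and count identity", {
  sp <- simulate_spike_fractions(cfg_small)
  expect_true(all(sp$spike_reads <= sp$spike_reads + sp$genome_reads))
  expect_true(all(sp$fraction >= 0.01 & sp$fraction <= 0.05))
  expect_identical(sp, simulate_spike_fractions(cfg_small))
  # degenerate range gives exact fractions
  cfg_exact <- sim_config(seed = 23, spike_fraction_range = c(0.01, 0.01))
  spx <- simulate_spike_fractions(cfg_exact)
  expect_equal(spx$fraction, rep(0.01, 6))
})

test_that("the full dataset writes consistent files and ground truth", {
  outdir <- withr::local_tempdir()
  ds <- simulate_dataset(cfg_small, outdir = outdir)
  expect_true(all(file.exists(unlist(ds$files))))
  # ground truth is verifiable against the emitted files
  peaks_back <- read_narrowpeak(ds$files$peaks)
  expect_equal(peaks_back$name, ds$peaks$name)
  tss_back <- read_tss_table(ds$files$tss)
  expect_equal(tss_back$gene_id, ds$tss$gene_id)
  truth <- jsonlite::read_json(ds$files$truth, simplifyVector = TRUE)
  expect_equal(nrow(truth$planted_motif_positions),
               nrow(ds$truth$planted_motif_positions))
  expect_true(all(truth$planted_motif_positions$peak_id %in% peaks_back$name))
  expect_true(all(names(ds$truth$gene_silencing_label) %in%
                    tss_back$gene_id |
                    length(ds$tss$gene_id) < cfg_small$n_genes))
  # byte-identical rerun
  outdir2 <- withr::local_tempdir()
  simulate_dataset(cfg_small, outdir = outdir2)
  for (f in list.files(outdir, full.names = FALSE)) {
    expect_identical(readLines(file.path(outdir, f)),
                     readLines(file.path(outdir2, f)))
  }
})
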
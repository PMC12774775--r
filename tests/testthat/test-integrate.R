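test_that("count prefiltering applies the >=10-in->=3-samples rule", {
  m <- rbind(exact = c(10, 10, 10, 0, 0, 0),
             near = c(9, 100, 100, 0, 0, 0),
             zero = c(0, 0, 0, 0, 0, 0),
             high = c(50, 50, 50, 50, 50, 50))
  out <- prefilter_counts(m)
  expect_equal(rownames(out), c("exact", "high"))
  expect_equal(attr(out, "n_removed"), 2)
  expect_error(prefilter_counts(m[, 1:2]), "3 samples")
})

test_that("DEG calls use strict inequalities and drop missing padj", {
  rec <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(0.31, 0.30, -2, -0.5, 1.2),
    padj = c(0.049, 0.001, NA, 0.03, 0.05),
    stringsAsFactors = FALSE)
  expect_setequal(call_degs(rec), c("a", "d"))
  expect_true("a" %in% call_degs(rec, direction = "increased"))
  expect_false("b" %in% call_degs(rec))    # |lfc| = 0.3 not > 0.3
  expect_false("c" %in% call_degs(rec))    # missing padj
  expect_false("e" %in% call_degs(rec))    # padj = 0.05 not < 0.05
  expect_true("d" %in% call_degs(rec, direction = "reduced"))
  # genotype contrast threshold
  expect_false("d" %in% call_degs(rec, lfc_min = deg_thresholds()$genotype_lfc_min))
  # strict preset lowers padj cutoff
  strict <- deg_thresholds(preset = "strict_agonist")
  expect_equal(strict$padj_max, 0.01)
  expect_length(call_degs(rec, strict), 0)  # b fails lfc, a fails padj
})

test_that("response classification recovers a hand-enumerated truth table", {
  # 8 genes covering agent-class x ko_responds cells at one time point
  tbl <- data.frame(
    gene = paste0("g", 1:8),
    time = "6h",
    par_cd = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    par_ra = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    ko_cd  = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    ko_ra  = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    direction = "increased",
    stringsAsFactors = FALSE)
  cls <- classify_response(make_deg_sets(tbl))
  got <- cls[match(paste0("g", 1:6), cls$gene_id), ]
  expect_equal(got$agent_class,
               c("BOTH", "BOTH", "CD1530_ONLY", "CD1530_ONLY",
                 "RA_ONLY", "RA_ONLY"))
  expect_equal(got$ko_responds, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  # g7: only KO responds -> no parental class; g8: nothing
  expect_false(any(cls$gene_id %in% c("g7", "g8")))
  # classes partition genes per (time, direction)
  expect_equal(anyDuplicated(cls[, c("gene_id", "time", "direction")]), 0L)
})

test_that("ko_responds requires the same direction at the same time", {
  deg_sets <- list(
    "6h" = list(
      PAR = list(CD1530 = list(increased = "g1"),
                 RA = list(increased = "g1")),
      KO = list(CD1530 = list(reduced = "g1"),  # wrong direction
                RA = list(increased = character(0)))),
    "48h" = list(
      PAR = list(CD1530 = list(increased = character(0)),
                 RA = list(increased = character(0))),
      KO = list(CD1530 = list(increased = "g1"),  # wrong time
                RA = list(increased = character(0)))))
  cls <- classify_response(deg_sets)
  row <- cls[cls$gene_id == "g1" & cls$time == "6h", ]
  expect_false(row$ko_responds)
})

test_that("peak filtering enforces q, KO overlap and top-n rules", {
  par <- make_peak_df("chr1", c(0, 1000, 2000, 3000),
                      c(200, 1200, 2200, 3200),
                      qvalue = c(10, 10, 10, 4.9))
  ko <- make_peak_df("chr1", c(190, 1170), c(390, 1370))
  cfg <- peak_filter_config(top_n = NULL)
  out <- filter_par_specific_peaks(par, ko, cfg)
  # peak1 overlaps KO by 10/200 = 5% -> retained; peak2 by 30/200 = 15% ->
  # removed; peak4 fails q regardless of overlap
  expect_setequal(out$name, c("pk1", "pk3"))
  # idempotence
  expect_equal(filter_par_specific_peaks(out, ko, cfg), out)
  # top-n by score with deterministic tie-break
  par2 <- make_peak_df("chr1", c(0, 500, 1000), c(100, 600, 1100),
                       score = c(700, 900, 700))
  out2 <- filter_par_specific_peaks(par2, ko[0, ],
                                    peak_filter_config(top_n = 2))
  expect_setequal(out2$name, c("pk1", "pk2"))  # tie at 700 -> earlier start
})

test_that("peak annotation matches a brute-force nearest-TSS oracle", {
  set.seed(171)
  tss <- data.frame(chrom = rep(c("chr1", "chr2"), each = 5),
                    start = rep(seq(10000, 50000, 10000), 2),
                    end = rep(seq(10000, 50000, 10000), 2) + 4000,
                    gene_id = paste0("g", 1:10), score = 0,
                    strand = sample(c("+", "-"), 10, TRUE),
                    stringsAsFactors = FALSE)
  tss$tss <- ifelse(tss$strand == "+", tss$start, tss$end - 1)
  peaks <- make_peak_df(sample(c("chr1", "chr2"), 50, TRUE),
                        start = sample(0:60000, 50), end = 0)
  peaks$end <- peaks$start + 300
  peaks$summit <- 150
  ann <- annotate_peaks(peaks, tss)
  for (i in 1:50) {
    cand <- tss[tss$chrom == peaks$chrom[i], ]
    d <- abs(peaks$start[i] + 150 - cand$tss)
    expect_equal(ann$links$gene_id[i], cand$gene_id[which.min(d)])
    expect_equal(abs(ann$links$distance[i]), min(d))
  }
  expect_equal(sum(ann$feature_distribution$fraction), 1)
})

test_that("tier boundaries are inclusive and summit-based", {
  tss <- data.frame(chrom = "chr1", start = 10000, end = 18000,
                    gene_id = "g1", score = 0, strand = "+", tss = 10000,
                    stringsAsFactors = FALSE)
  mk <- function(summit_abs) {
    make_peak_df("chr1", summit_abs - 100, summit_abs + 100, summit = 100)
  }
  at <- function(s) annotate_peaks(mk(s), tss)$links
  expect_equal(at(10000)$tier, "proximal_promoter")  # distance 0
  expect_equal(at(10000)$distance, 0)
  expect_equal(at(10250)$tier, "proximal_promoter")  # exactly 250
  expect_equal(at(10251)$tier, "cre")                # 251 -> CRE
  expect_equal(at(13000)$tier, "cre")                # exactly 3000
  expect_equal(at(13001)$tier, "gene_body")          # in span, > 3000
  expect_equal(at(50000)$tier, "distal")
  # minus-strand sign convention: negative = upstream of the TSS
  tss_m <- transform(tss, strand = "-", tss = 17999)
  expect_equal(annotate_peaks(mk(18100), tss_m)$links$distance, -101)
  expect_warning(annotate_peaks(make_peak_df("chrX", 0, 200), tss),
                 "absent")
})

test_that("the tier table recovers a constructed truth fixture exactly", {
  # 20 genes: classes and links chosen so every nested column differs
  genes <- sprintf("G%02d", 1:20)
  cls <- data.frame(
    gene_id = genes, time = "48h",
    agent_class = rep(c("BOTH", "CD1530_ONLY", "RA_ONLY", "BOTH"), 5),
    direction = rep(c("reduced", "increased"), 10),
    ko_responds = rep(c(TRUE, TRUE, FALSE, FALSE), 5),
    stringsAsFactors = FALSE)
  # links: genes 1-12 have peaks; 1-8 at cre or closer; 1-4 proximal
  links <- data.frame(
    peak_id = sprintf("p%02d", 1:12),
    gene_id = genes[1:12],
    distance = c(rep(100, 4), rep(2000, 4), rep(9000, 4)),
    tier = c(rep("proximal_promoter", 4), rep("cre", 4),
             rep("distal", 4)),
    stringsAsFactors = FALSE)
  tt <- build_tier_table(cls, links)
  # every row verified against direct set counting
  for (i in seq_len(nrow(tt))) {
    sel <- cls$agent_class == tt$agent_class[i] &
      cls$direction == tt$direction[i] & cls$ko_responds == tt$ko_responds[i]
    g <- cls$gene_id[sel]
    expect_equal(tt$total_degs[i], length(g))
    expect_equal(tt$with_peaks[i], sum(g %in% genes[1:12]))
    expect_equal(tt$with_cre[i], sum(g %in% genes[1:8]))
    expect_equal(tt$with_proximal[i], sum(g %in% genes[1:4]))
  }
  # empty input gives an all-zero table
  tt0 <- build_tier_table(cls[0, ], links)
  expect_true(all(tt0$total_degs == 0))
})

test_that("tier-table nesting monotonicity holds on random fixtures", {
  set.seed(181)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    genes <- sprintf("g%d", seq_len(n))
    cls <- data.frame(
      gene_id = genes,
      time = sample(c("6h", "48h"), n, TRUE),
      agent_class = sample(c("BOTH", "CD1530_ONLY", "RA_ONLY"), n, TRUE),
      direction = sample(c("increased", "reduced"), n, TRUE),
      ko_responds = sample(c(TRUE, FALSE), n, TRUE),
      stringsAsFactors = FALSE)
    nl <- sample(0:n, 1)
    links <- data.frame(
      peak_id = sprintf("p%d", seq_len(nl)),
      gene_id = sample(genes, nl, replace = TRUE),
      distance = numeric(nl),
      tier = sample(c("proximal_promoter", "cre", "gene_body", "distal"),
                    nl, TRUE),
      stringsAsFactors = FALSE)
    tt <- build_tier_table(cls, links)
    expect_true(all(tt$total_degs >= tt$with_peaks))
    expect_true(all(tt$with_peaks >= tt$with_cre))
    expect_true(all(tt$with_cre >= tt$with_proximal))
    expect_true(all(tt$with_proximal >= 0))
    expect_equal(sum(tt$total_degs), n)  # classes partition the genes
  }
})

test_that("silencing calls follow the <10 / >50 normalized-count rule", {
  par <- c(MUC4 = 250, a = 9, b = 30, c = 60, d = 8)
  ko <- c(MUC4 = 3, a = 60, b = 30, c = 55, d = 9)
  out <- silencing_calls(par, ko)
  expect_equal(out$label,
               c("silenced_in_ko", "activated_in_ko", "neither", "neither",
                 "neither"))
  expect_error(silencing_thresholds(60, 50), "below")
})
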
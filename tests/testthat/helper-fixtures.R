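# shared fixtures built in code

HALF <- pfm_from_consensus("RGKTCA")

random_dna <- function(n, len, gc = 0.5, prefix = "s") {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  names(out) <- sprintf("%s_%d", prefix, seq_len(n))
  out
}

# plant a literal string at a 0-based offset
plant_string <- function(seq, insert, offset0) {
  paste0(substr(seq, 1, offset0), insert,
         substr(seq, offset0 + nchar(insert) + 1, nchar(seq)))
}

# independent brute-force window scorer (R, no shared code with the scanner)
brute_force_scan <- function(seq, prob_mat, background = rep(0.25, 4),
                             pseudocount = 1e-4, hit_fraction = 0.7) {
  bases <- c("A", "C", "G", "T")
  lo <- log2((prob_mat + pseudocount) / (background + pseudocount))
  w <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  thr <- hit_fraction * max_score
  chars <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- NULL
  for (i in seq_len(length(chars) - w + 1)) {
    win <- chars[i:(i + w - 1)]
    sc_f <- 0
    sc_r <- 0
    for (j in seq_len(w)) {
      b <- win[j]
      if (b %in% bases) sc_f <- sc_f + lo[match(b, bases), j]
      rb <- comp[win[w - j + 1]]
      if (!is.na(rb) && rb %in% bases) sc_r <- sc_r + lo[match(rb, bases), j]
    }
    if (sc_f >= thr) hits <- rbind(hits, data.frame(offset = i - 1,
                                                    strand = "+",
                                                    score = sc_f))
    if (sc_r >= thr) hits <- rbind(hits, data.frame(offset = i - 1,
                                                    strand = "-",
                                                    score = sc_r))
  }
  hits
}

# exact upper-tail binomial by direct summation
binom_upper_oracle <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# one-sided hypergeometric tail for the 2x2 table [[kt, nt-kt],[kb, nb-kb]]
fisher_oracle <- function(kt, nt, kb, nb) {
  K <- kt + kb           # total successes
  N <- nt + nb
  kmax <- min(K, nt)
  probs <- vapply(0:kmax, function(x) {
    choose(K, x) * choose(N - K, nt - x) / choose(N, nt)
  }, numeric(1))
  sum(probs[(kt:kmax) + 1])
}

# exact one-sided Mann-Whitney p by full enumeration of group assignments
ranksum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(us >= u_obs)
}

# a minimal genotype x agent x time DEG fixture covering all class cells
make_deg_sets <- function(tbl) {
  # tbl: data.frame gene, time, par_cd, par_ra, ko_cd, ko_ra, direction
  out <- list()
  for (tm in unique(tbl$time)) {
    for (dir in c("increased", "reduced")) {
      sub <- tbl[tbl$time == tm & tbl$direction == dir, , drop = FALSE]
      out[[tm]][["PAR"]][["CD1530"]][[dir]] <- sub$gene[sub$par_cd]
      out[[tm]][["PAR"]][["RA"]][[dir]] <- sub$gene[sub$par_ra]
      out[[tm]][["KO"]][["CD1530"]][[dir]] <- sub$gene[sub$ko_cd]
      out[[tm]][["KO"]][["RA"]][[dir]] <- sub$gene[sub$ko_ra]
    }
  }
  out
}

make_peak_df <- function(chrom, start, end, name = NULL, score = 500,
                         qvalue = 10, summit = NULL) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             name = name %||% sprintf("pk%d", seq_len(n)),
             score = rep_len(score, n), strand = ".",
             signal = 5, pvalue = 12, qvalue = rep_len(qvalue, n),
             summit = summit %||% ((end - start) %/% 2),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
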
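test_that("consensus expansion follows IUPAC", {
  expect_equal(unclass(pfm_from_consensus("A"))[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unclass(pfm_from_consensus("R"))[, 1], c(A = 0.5, C = 0, G = 0.5, T = 0))
  half <- pfm_from_consensus("RGKTCA")
  expect_equal(ncol(half), 6)
  k_col <- unclass(half)[, 3]
  expect_equal(sum(k_col > 0), 2)          # K splits mass over two bases
  expect_equal(unname(k_col[c("G", "T")]), c(0.5, 0.5))
  expect_error(pfm_from_consensus("AXG"), "non-IUPAC")
})

test_that("every pfm transformation preserves column stochasticity", {
  set.seed(42)
  for (rep in 1:10) {
    w <- sample(3:10, 1)
    m <- matrix(stats::rexp(4 * w), nrow = 4)
    m <- sweep(m, 2, colSums(m), "/")
    p <- pfm(m)
    for (res in list(pfm_reverse_complement(p),
                     trim_to_core(p, sample(seq_len(w), 1)),
                     build_repeat(p, "ER", 4)$composite)) {
      expect_equal(colSums(unclass(res)), rep(1, ncol(res)), tolerance = 1e-9)
    }
  }
})

test_that("trim_to_core selects the max-IC window, leftmost on ties", {
  flank <- matrix(0.25, 4, 4)
  core <- unclass(pfm_from_consensus("ACGTAC"))
  p <- pfm(cbind(flank, core, flank), name = "padded")
  expect_equal(unclass(trim_to_core(p, 6)), core, ignore_attr = TRUE)
  # identity when core_width equals width
  expect_equal(unclass(trim_to_core(p, ncol(p))), unclass(p),
               ignore_attr = TRUE)
  expect_error(trim_to_core(p, ncol(p) + 1), "exceeds")
  # tie case: two identical informative windows -> leftmost, checked
  # against an exhaustive window-scoring oracle
  tie <- pfm(cbind(core[, 1:2], matrix(0.25, 4, 3), core[, 1:2]))
  ic <- apply(unclass(tie), 2, function(x) {
    x <- x[x > 0]; 2 + sum(x * log2(x))
  })
  totals <- vapply(1:(ncol(tie) - 1), function(i) sum(ic[i:(i + 1)]),
                   numeric(1))
  expect_equal(unclass(trim_to_core(tie, 2)),
               unclass(tie)[, which.max(totals) + 0:1], ignore_attr = TRUE)
  expect_equal(which.max(totals), 1L)  # leftmost of the tied windows
  # explicit window slice
  expect_equal(unclass(trim_to_core(p, window = 5:10)), core,
               ignore_attr = TRUE)
})

test_that("reverse complement is an involution with the right consensus", {
  half <- pfm_from_consensus("RGKTCA")
  expect_equal(unclass(pfm_reverse_complement(pfm_reverse_complement(half))),
               unclass(half), ignore_attr = TRUE)
  expect_equal(unclass(pfm_reverse_complement(half)),
               unclass(pfm_from_consensus("TGAMCY")), ignore_attr = TRUE)
  pal <- pfm_from_consensus("ACGT")  # reverse-complement palindrome
  expect_equal(unclass(pfm_reverse_complement(pal)), unclass(pal),
               ignore_attr = TRUE)
})

test_that("repeat construction obeys the width law and orientations", {
  set.seed(7)
  for (w in c(4, 6, 9)) {
    m <- matrix(stats::rexp(4 * w), nrow = 4)
    half <- pfm(sweep(m, 2, colSums(m), "/"))
    for (kind in c("DR", "ER", "IR")) {
      for (n in 0:12) {
        rm <- build_repeat(half, kind, n)
        expect_equal(ncol(rm$composite), 2 * w + n)
        expect_equal(rm$label, paste0(kind, n))
      }
    }
  }
  half <- pfm_from_consensus("RGKTCA")
  dr5 <- build_repeat(half, "DR", 5)
  expect_equal(ncol(dr5$composite), 17)
  er8 <- build_repeat(half, "ER", 8)
  expect_equal(ncol(er8$composite), 20)
  expect_equal(unclass(er8$composite)[, 1:6],
               unclass(pfm_reverse_complement(half)), ignore_attr = TRUE)
  ir <- build_repeat(half, "IR", 2)
  expect_equal(unclass(ir$composite)[, 9:14],
               unclass(pfm_reverse_complement(half)), ignore_attr = TRUE)
  # spacer columns equal the background
  expect_equal(unclass(dr5$composite)[, 7:11],
               matrix(0.25, 4, 5), ignore_attr = TRUE)
  expect_error(build_repeat(half, "DR", -1), "non-negative")
})

test_that("IR0 of a palindromic half-site is self-reverse-complementary", {
  pal <- pfm_from_consensus("ACGT")
  ir0 <- build_repeat(pal, "IR", 0)
  expect_equal(unclass(pfm_reverse_complement(ir0$composite)),
               unclass(ir0$composite), ignore_attr = TRUE)
})

test_that("DR family is strand symmetric as a set", {
  half <- pfm_from_consensus("RGGTCA")
  dr3 <- build_repeat(half, "DR", 3)$composite
  dr3_rc_half <- build_repeat(pfm_reverse_complement(half), "DR", 3)$composite
  expect_equal(unclass(pfm_reverse_complement(dr3)), unclass(dr3_rc_half),
               ignore_attr = TRUE)
})

test_that("log-odds scores, max score and hit threshold are correct", {
  cfg0 <- scan_config(pseudocount = 0)
  onehot <- pfm_from_consensus("ACGTAC")
  sm <- to_log_odds(onehot, cfg0)
  expect_equal(unname(unclass(sm)[1, 1]), 2)  # log2(1 / 0.25)
  expect_equal(attr(sm, "max_score"), 12)
  expect_equal(attr(sm, "hit_threshold"), 8.4)
  unif <- pfm(matrix(0.25, 4, 5))
  smu <- to_log_odds(unif, cfg0)
  expect_true(all(unclass(smu) == 0))
  expect_equal(attr(smu, "max_score"), 0)
  # a background-equal column scores exactly 0 with zero pseudocount
  bg <- c(0.3, 0.2, 0.2, 0.3)
  smb <- to_log_odds(pfm(matrix(bg, 4, 2)),
                     scan_config(pseudocount = 0, background = bg))
  expect_true(all(abs(unclass(smb)) < 1e-12))
  expect_error(to_log_odds(onehot, scan_config(pseudocount = 0,
                                               background = c(1, 0, 0, 0))),
               "zero")
})

test_that("log-odds is monotone in base probability", {
  set.seed(11)
  for (rep in 1:20) {
    p <- stats::runif(1, 0.05, 0.8)
    delta <- stats::runif(1, 0, 0.2)
    col1 <- c(p, (1 - p) / 3, (1 - p) / 3, (1 - p) / 3)
    p2 <- p + delta
    col2 <- c(p2, (1 - p2) / 3, (1 - p2) / 3, (1 - p2) / 3)
    s1 <- unclass(to_log_odds(pfm(matrix(col1))))[1, 1]
    s2 <- unclass(to_log_odds(pfm(matrix(col2))))[1, 1]
    expect_gte(s2, s1)
  }
})

test_that("pfm validation rejects malformed matrices", {
  expect_error(pfm(matrix(0.25, 3, 4)), "4 rows")
  expect_error(pfm(matrix(c(0.5, 0.5, 0.5, 0.5), 4, 1)), "sum to 1")
  expect_error(pfm(matrix(c(1.5, -0.5, 0, 0), 4, 1)), "non-negative")
})
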
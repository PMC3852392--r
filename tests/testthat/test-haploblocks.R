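# diploid genotypes from explicit haplotype pairs
geno_from_haps <- function(h1, h2) h1 + h2

test_that("two-locus EM recovers haplotype frequencies", {
  # perfectly correlated markers -> D' = 1
  g <- c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 2L, 1L, 2L)
  em <- two_locus_em(g, g)
  expect_equal(sum(em$freqs), 1)
  expect_equal(unname(em$freqs["h10"] + em$freqs["h01"]), 0, tolerance = 1e-7)
  pl <- dprime_ci(em)
  expect_equal(pl$dprime, 1, tolerance = 1e-6)

  # independent markers with exactly balanced haplotype counts -> D' = 0
  # 25 of each haplotype phased into 25 individuals per combination class
  set.seed(5)
  hap <- cbind(rep(c(1, 1, 0, 0), each = 25), rep(c(1, 0, 1, 0), each = 25))
  idx <- matrix(sample(100), ncol = 2)   # random pairing into 50 diploids
  g1 <- hap[idx[, 1], 1] + hap[idx[, 2], 1]
  g2 <- hap[idx[, 1], 2] + hap[idx[, 2], 2]
  em2 <- two_locus_em(as.integer(g1), as.integer(g2))
  expect_equal(unname(em2$p), mean(g1) / 2)       # marginals exact
  expect_equal(unname(em2$q), mean(g2) / 2)
  expect_equal(max(abs(em2$freqs - 0.25)), 0, tolerance = 0.02)

  # known phased truth with unequal frequencies, recovered within 0.02
  set.seed(8)
  hfreq <- c(0.45, 0.25, 0.2, 0.1)   # h11 h10 h01 h00
  hmat <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  draw <- sample(1:4, 400, replace = TRUE, prob = hfreq)
  realized <- tabulate(draw, 4) / 400   # the truth is the drawn counts
  h <- hmat[draw, ]
  g1 <- h[seq(1, 399, 2), 1] + h[seq(2, 400, 2), 1]
  g2 <- h[seq(1, 399, 2), 2] + h[seq(2, 400, 2), 2]
  em3 <- two_locus_em(as.integer(g1), as.integer(g2))
  expect_lt(max(abs(em3$freqs - realized)), 0.02)

  # insufficient data flagged uninformative
  expect_false(two_locus_em(c(0L, NA), c(NA, 1L))$informative)
  expect_false(two_locus_em(rep(0L, 10), rep(1L, 10))$informative)
})

test_that("D' confidence intervals classify pairs as in the block definition", {
  # complete LD with many chromosomes: strong LD (CI collapses near 1)
  g <- rep(c(0L, 1L, 2L), each = 20)
  pl <- dprime_ci(two_locus_em(g, g))
  expect_equal(pl$class, "strong_LD")
  expect_gte(pl$ci_low, 0.70)
  expect_gte(pl$ci_high, 0.98)

  # near-equilibrium with many chromosomes: strong evidence of recombination
  set.seed(12)
  h1 <- rbinom(2000, 1, 0.5); h2 <- rbinom(2000, 1, 0.5)
  g1 <- h1[1:1000] + h1[1001:2000]; g2 <- h2[1:1000] + h2[1001:2000]
  pl2 <- dprime_ci(two_locus_em(as.integer(g1), as.integer(g2)))
  expect_equal(pl2$class, "recombination")
  expect_lt(pl2$ci_high, 0.90)

  # tiny sample: the likelihood profile is too wide to call either way even
  # though the point estimate of D-prime is 1
  g1 <- c(2L, 1L, 0L, 0L, 0L, 2L, 1L, 2L, 0L, 1L)
  g2 <- c(0L, 0L, 2L, 0L, 1L, 0L, 1L, 0L, 2L, 1L)
  pl3 <- dprime_ci(two_locus_em(g1, g2))
  expect_equal(pl3$class, "uninformative")
  expect_lt(pl3$ci_low, 0.70)

  # monomorphic marker is uninformative
  expect_equal(dprime_ci(two_locus_em(rep(1L, 20), rep(0L, 20)))$class,
               "uninformative")
})

# panel with a planted identical-haplotype segment: within the segment every
# individual carries one of two complementary haplotypes; outside, markers
# segregate independently
planted_panel <- function(n_ind = 40, n_markers = 60, seg = 21:40,
                          span_bp = 1e7, seed = 99) {
  set.seed(seed)
  pos <- as.integer(seq(1e5, span_bp, length.out = n_markers))
  map <- tibble::tibble(marker_id = paste0("s", seq_len(n_markers)),
                        chrom = "1", pos_bp = pos,
                        allele_ref = "A", allele_alt = "C")
  hapA <- rep(c(1L, 0L), length.out = length(seg))
  draw_hap <- function() {
    h <- as.integer(rbinom(n_markers, 1, 0.5))
    h[seg] <- if (runif(1) < 0.5) hapA else 1L - hapA
    h
  }
  g <- t(vapply(seq_len(n_ind), function(i) draw_hap() + draw_hap(),
                integer(n_markers)))
  rownames(g) <- paste0("i", seq_len(n_ind))
  gt_panel(map, list(pop = g))
}

test_that("block calling finds planted segments and nothing in equilibrium", {
  # 3 SNPs in complete mutual LD -> one block covering all 3
  set.seed(44)
  h <- rbinom(40, 1, 0.5)
  g <- matrix(as.integer(h[1:20] + h[21:40]), ncol = 1)[, c(1, 1, 1)]
  rownames(g) <- paste0("i", 1:20)
  p3 <- gt_panel(make_map(3), list(pop = g))
  b3 <- call_blocks(p3, "pop")
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$n_markers, 3L)

  # markers in linkage equilibrium -> zero blocks
  set.seed(45)
  ge <- matrix(as.integer(rbinom(30 * 20, 2, 0.5)), nrow = 30)
  rownames(ge) <- paste0("i", 1:30)
  pe <- gt_panel(make_map(20), list(pop = ge))
  expect_equal(nrow(call_blocks(pe, "pop")), 0L)

  # planted 6.6 Mb two-haplotype segment inside a 20 Mb chromosome
  pp <- planted_panel(span_bp = 2e7, seg = 21:40)
  bp <- call_blocks(pp, "pop")
  expect_gte(nrow(bp), 1L)
  big <- filter_large_blocks(bp, 5e6)
  expect_equal(nrow(big), 1L)
  seg_lo <- pp$map$pos_bp[21]; seg_hi <- pp$map$pos_bp[40]
  spacing <- diff(pp$map$pos_bp[1:2])
  expect_lte(abs(big$start_bp - seg_lo), spacing)  # boundaries within 1 marker
  expect_lte(abs(big$end_bp - seg_hi), spacing)

  # output invariants: blocks non-overlapping, outermost pair strong
  if (nrow(bp) > 1) {
    bp <- bp[order(bp$start_bp), ]
    expect_true(all(bp$start_bp[-1] > bp$end_bp[-nrow(bp)]))
  }
  i <- match(big$start_bp, pp$map$pos_bp)
  j <- match(big$end_bp, pp$map$pos_bp)
  pl <- dprime_ci(two_locus_em(pp$geno$pop[, i], pp$geno$pop[, j]))
  expect_equal(pl$class, "strong_LD")
})

test_that("large-block filter is strict and sorted", {
  blocks <- tibble::tibble(population = "p", chrom = c("2", "1", "1"),
                           start_bp = c(1e6, 9548e4, 1e5),
                           end_bp = c(6e6, 101.85e6, 2e5),
                           n_markers = c(10L, 12L, 3L),
                           span_bp = c(5e6, 6.37e6, 1e5))
  out <- filter_large_blocks(blocks, 5e6)
  expect_equal(nrow(out), 1L)              # 5.0 Mb exactly is excluded
  expect_equal(out$span_bp, 6.37e6)        # 95.48-101.85 Mb style block kept
  expect_equal(nrow(filter_large_blocks(blocks[0, ], 5e6)), 0L)
})
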
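test_that("marker heterozygosity follows 2m(1-m) and rejects bad input", {
  expect_equal(marker_het(0.5), 0.5)
  expect_equal(marker_het(1), 0)
  expect_equal(marker_het(0.8), 0.32)
  set.seed(42)
  m <- runif(1000)
  expect_equal(marker_het(m), 1 - (m^2 + (1 - m)^2))  # algebraic identity
  expect_equal(marker_het(m), marker_het(1 - m))      # symmetry
  expect_error(marker_het(1.2), "outside")
  expect_true(is.na(marker_het(NA)))
})

test_that("window profile equals brute-force window means per chromosome", {
  cfg <- scan_config(W = 3, step = 1)
  pr <- window_profile(hz_tbl(c(0.1, 0.2, 0.3, 0.4)), cfg)
  expect_equal(pr$hz_mean, c(0.2, 0.3))
  expect_equal(pr$first, 1:2)

  # constant input -> constant windows
  prc <- window_profile(hz_tbl(rep(0.31, 10)), cfg)
  expect_equal(prc$hz_mean, rep(0.31, 8))

  # windows never span a chromosome boundary
  two <- rbind(hz_tbl(c(0.1, 0.2, 0.3), chrom = "1"),
               hz_tbl(c(0.4, 0.5, 0.6), chrom = "2"))
  pr2 <- window_profile(two, cfg)
  expect_equal(nrow(pr2), 2L)
  expect_equal(pr2$hz_mean, c(0.2, 0.5))

  # random vectors against direct recomputation, including NA renormalization
  set.seed(9)
  x <- runif(40, 0, 0.5)
  x[c(5, 17, 18)] <- NA
  W <- 7
  got <- window_profile(hz_tbl(x), scan_config(W = W))$hz_mean
  want <- vapply(seq_len(40 - W + 1), function(i) {
    mean(x[i:(i + W - 1)], na.rm = TRUE)
  }, numeric(1))
  expect_equal(got, want)

  # chromosome shorter than W is skipped with a warning
  expect_warning(window_profile(hz_tbl(c(0.1, 0.2)), scan_config(W = 5)),
                 "fewer than W")
})

test_that("profile differences and changes behave like signed vectors", {
  cfg <- scan_config(W = 2)
  a <- window_profile(hz_tbl(rep(0.4, 6), pop = "a"), cfg)
  b <- window_profile(hz_tbl(rep(0.1, 6), pop = "b"), cfg)
  d <- profile_difference(a, b)
  expect_equal(d$diff, rep(0.3, 5))
  expect_equal(profile_difference(b, a)$diff, -d$diff)  # antisymmetry
  expect_true(all(profile_difference(a, a)$diff == 0))

  ch <- profile_change(d, d)
  expect_true(all(ch$change == 0))
  zero <- d; zero$diff <- 0
  expect_equal(profile_change(zero, d)$change, d$diff)
  expect_equal(profile_change(d, zero)$change, -profile_change(zero, d)$change)

  short <- window_profile(hz_tbl(rep(0.4, 5), pop = "a"), cfg)
  expect_error(profile_difference(short, b), "window grid")
})

test_that("empirical threshold implements the Bonferroni-corrected normal cut", {
  cfg <- scan_config(W = 100, alpha = 0.05)
  # 55,983 markers need 560 nonoverlapping windows of 100
  thr <- empirical_threshold(rnorm(1000), cfg, n_markers = 55983)
  expect_identical(thr$n_indep, 560L)
  expect_equal(thr$q, 0.025 / 560)

  # standard-normal change vector: cut approaches Phi^-1(q) = -3.918
  # (scipy.stats.norm.ppf(0.025/560) = -3.9180026787853977)
  z <- (seq_len(20001) - 10001) / 10001 * 5
  z <- qnorm(pnorm(z))  # arbitrary symmetric vector with mean 0
  thr2 <- empirical_threshold(z / sd(z), cfg, 55983)
  expect_equal(thr2$lower, -3.9180026787853977, tolerance = 1e-6)
  expect_equal(thr2$upper, -thr2$lower, tolerance = 1e-10)

  # per-tail q = 0.5 puts both cuts at the mean
  thr3 <- empirical_threshold(c(-1, 0, 1), scan_config(W = 1, alpha = 1 - 1e-12),
                              n_markers = 1)
  expect_equal(thr3$lower, thr3$mu, tolerance = 1e-5)

  expect_error(empirical_threshold(rep(0.2, 10), cfg, 100), "degenerate")
})

test_that("region calling merges flagged runs and respects strict cuts", {
  grid <- window_profile(hz_tbl(rep(0.2, 12)), scan_config(W = 2))
  ch <- grid[, c("chrom", "first", "last", "start_bp", "end_bp", "mid_bp")]

  ch$change <- 0
  expect_equal(nrow(call_regions(ch, c(-1, 1))), 0L)

  # one isolated flagged window spans exactly that window's markers
  ch$change <- c(0, 0, 0, 2, 0, 0, 0, 0, 0, 0, 0)
  r1 <- call_regions(ch, c(-1, 1))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$direction, "gain")
  expect_equal(c(r1$start_bp, r1$end_bp), c(ch$start_bp[4], ch$end_bp[4]))

  # ties at the cut are not flagged (strict inequality)
  ch$change <- c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(nrow(call_regions(ch, c(-1, 1))), 0L)

  # adjacent same-sign windows merge; opposite signs stay separate
  ch$change <- c(-2, -2, -2, 0, 0, 2, 2, 0, 0, -2, 0)
  r2 <- call_regions(ch, c(-1, 1))
  expect_equal(nrow(r2), 3L)
  expect_equal(r2$direction[order(r2$start_bp)], c("loss", "gain", "loss"))
  expect_equal(sum(r2$n_windows), 6L)
  # regions are disjoint and sorted
  expect_true(all(diff(r2$start_bp) > 0))
  expect_true(all(r2$end_bp[-3] < r2$start_bp[-1]))

  # flagged windows that share markers merge even across an index gap
  grid4 <- window_profile(hz_tbl(rep(0.2, 12)), scan_config(W = 4))
  ch4 <- grid4[, c("chrom", "first", "last", "start_bp", "end_bp", "mid_bp")]
  ch4$change <- c(0, 2, 0, 0, 2, 0, 0, 0, 0)   # windows 2 (2-5) and 5 (5-8)
  r4 <- call_regions(ch4, c(-1, 1))
  expect_equal(nrow(r4), 1L)
  expect_equal(c(r4$first, r4$last), c(2L, 8L))
})

test_that("timeline rule table matches the two-line design semantics", {
  base <- c(HWS40 = 0.3, HWS50 = 0.3, HWS53 = 0.3, HWR9 = 0.3,
            LWS40 = 0.3, LWS50 = 0.3, LWS53 = 0.3, LWR9 = 0.3)
  region <- list(chrom = "1", first = 5L, last = 12L)
  cfg <- scan_config()
  call <- function(levels) {
    classify_timeline(region, constant_profiles(levels), cfg = cfg)
  }

  # all polymorphic -> not fixed
  expect_equal(call(base)$rule, "e")

  # fixed in both lines at generation 40 -> shared event before 40
  lv <- base; lv[c("HWS40", "LWS40")] <- 0.001
  out_a <- call(lv)
  expect_equal(out_a$rule, "a")
  expect_equal(out_a$lineage, "both")
  expect_equal(out_a$onset_hi, 40)

  # polymorphic at 40, fixed at 50/53, reduced in the relaxed line:
  # onset (40,45], fixation (45,50] in the HW lineage only
  lv <- base
  lv[c("HWS50", "HWS53")] <- 0.001
  lv["HWR9"] <- 0.1           # below half the genome median (0.15), not fixed
  out_c <- call(lv)
  expect_equal(out_c$rule, "c")
  expect_equal(out_c$lineage, "HW")
  expect_equal(c(out_c$onset_lo, out_c$onset_hi), c(40, 45))
  expect_equal(c(out_c$fixation_lo, out_c$fixation_hi), c(45, 50))

  # relaxed line also fixed -> fixation may predate the split (rule b)
  lv["HWR9"] <- 0.001
  out_b <- call(lv)
  expect_equal(out_b$rule, "b")
  expect_equal(c(out_b$onset_lo, out_b$onset_hi), c(40, 45))

  # fixed only in the last generation (rule d), here in the LW lineage
  lv <- base; lv["LWS53"] <- 0.001
  out_d <- call(lv)
  expect_equal(out_d$rule, "d")
  expect_equal(out_d$lineage, "LW")
  expect_equal(c(out_d$fixation_lo, out_d$fixation_hi), c(50, 53))

  # a subgroup missing from the profiles is a hard error
  pr <- constant_profiles(base)
  expect_error(
    classify_timeline(region, pr[pr$population != "LWR9", ], cfg = cfg),
    "LWR9")
})
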
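#' Two-locus haplotype frequencies from unphased diploid genotypes
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic markers
#' via expectation-maximization over the phase of double heterozygotes,
#' assuming random union of gametes. Convergence when the largest frequency
#' change is below 1e-8, or after 1000 iterations.
#'
#' @param g1,g2 Alt-allele dosage vectors (0/1/2, `NA` missing) over the
#'   same individuals.
#' @return List: `freqs` (named numeric: `h11`, `h10`, `h01`, `h00` where
#'   "1" is the alt allele; sums to 1 and reproduces the single-locus allele
#'   frequencies exactly), `p` and `q` (alt-allele frequencies at locus 1
#'   and 2), `n` (double-called individuals), `counts` (the 3x3 genotype
#'   count table), `informative` (`FALSE` when fewer than 2 double-called
#'   individuals or either locus is monomorphic among them).
#' @export
two_locus_em <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  cnt <- matrix(0, 3, 3)  # rows g1 dosage 0..2, cols g2 dosage 0..2
  for (i in seq_len(n)) cnt[g1[i] + 1, g2[i] + 1] <- cnt[g1[i] + 1, g2[i] + 1] + 1
  p <- sum(g1) / (2 * n); q <- sum(g2) / (2 * n)
  out <- list(freqs = c(h11 = p * q, h10 = p * (1 - q),
                        h01 = (1 - p) * q, h00 = (1 - p) * (1 - q)),
              p = p, q = q, n = n, counts = cnt, informative = TRUE)
  if (n < 2 || p %in% c(0, 1) || q %in% c(0, 1)) {
    out$informative <- FALSE
    return(out)
  }
  h <- out$freqs
  nDH <- cnt[2, 2]
  base11 <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
  base10 <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
  base01 <- 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2]
  base00 <- 2 * cnt[1, 1] + cnt[2, 1] + cnt[1, 2]
  for (it in seq_len(1000)) {
    cis <- h["h11"] * h["h00"]
    trans <- h["h10"] * h["h01"]
    pc <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new <- c(base11 + nDH * pc, base10 + nDH * (1 - pc),
             base01 + nDH * (1 - pc), base00 + nDH * pc) / (2 * n)
    names(new) <- names(h)
    if (max(abs(new - h)) < 1e-8) { h <- new; break }
    h <- new
  }
  out$freqs <- h
  out
}

#' D-prime and its confidence interval for one marker pair
#'
#' Computes `|D'|` from two-locus haplotype frequencies and a confidence
#' interval by the likelihood-profile method used in the Gabriel block
#' definition: the likelihood of the estimated haplotype counts is evaluated
#' on a grid of `|D'|` in \[0, 1\] (allele frequencies held fixed),
#' normalized, and the 5th and 95th percentiles of the cumulative likelihood
#' taken as `ci_low` and `ci_high`. Classification: `strong_LD` when
#' `ci_low >= 0.70` and `ci_high >= 0.98`; `recombination` when
#' `ci_high < 0.90`; otherwise `uninformative`.
#'
#' @param em Result of [two_locus_em()].
#' @param n_chromosomes Number of gametes behind the estimate (default
#'   `2 * em$n`).
#' @return One-row tibble: `dprime`, `ci_low`, `ci_high`, `class`.
#' @export
dprime_ci <- function(em, n_chromosomes = 2 * em$n) {
  uninf <- tibble::tibble(dprime = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, class = "uninformative")
  if (!isTRUE(em$informative)) return(uninf)
  p <- em$p; q <- em$q
  D <- em$freqs[["h11"]] - p * q
  dmax <- if (D >= 0) min(p * (1 - q), (1 - p) * q) else min(p * q, (1 - p) * (1 - q))
  if (dmax <= 0) return(uninf)
  dprime <- abs(D) / dmax
  s <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, by = 0.001)
  counts <- em$freqs * n_chromosomes
  ll <- vapply(grid, function(dp) {
    Dg <- s * dp * dmax
    h <- c(p * q + Dg, p * (1 - q) - Dg, (1 - p) * q - Dg, (1 - p) * (1 - q) + Dg)
    h <- pmax(h, 1e-12)
    sum(counts * log(h))
  }, numeric(1))
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  ci_low <- grid[which(cum >= 0.05)[1]]
  ci_high <- grid[which(cum >= 0.95)[1]]
  cls <- if (ci_low >= 0.70 && ci_high >= 0.98) "strong_LD"
         else if (ci_high < 0.90) "recombination"
         else "uninformative"
  tibble::tibble(dprime = min(dprime, 1), ci_low = ci_low, ci_high = ci_high,
                 class = cls)
}

#' Call haplotype blocks with the Gabriel confidence-interval definition
#'
#' For one population, evaluates pairwise `|D'|` confidence intervals for
#' all marker pairs closer than `max_pair_bp`, then calls blocks by the
#' spanning rule: a candidate block is a marker interval whose outermost
#' pair is in strong LD and in which at least `strong_fraction` of
#' informative pairs (strong LD or strong recombination) are strong LD.
#' Overlapping candidates are resolved longest-span-first. Markers with
#' minor allele frequency below `maf_floor` are excluded from the analysis.
#'
#' @param panel A [gt_panel()].
#' @param population Population id.
#' @param max_pair_bp Pairs farther apart than this are never evaluated
#'   (default 10 Mb).
#' @param maf_floor Minimum minor allele frequency for a marker to enter the
#'   analysis (default 0.05).
#' @param strong_fraction Minimum fraction of informative pairs in strong LD
#'   (default 0.95).
#' @param min_markers Minimum markers per block (default 2).
#' @return Tibble of blocks: `population`, `chrom`, `start_bp`, `end_bp`,
#'   `n_markers`, `span_bp`, sorted by chromosome then start. Blocks are
#'   non-overlapping and each block's outermost pair is strong LD.
#' @export
call_blocks <- function(panel, population, max_pair_bp = 10e6,
                        maf_floor = 0.05, strong_fraction = 0.95,
                        min_markers = 2) {
  g <- panel$geno[[population]]
  if (is.null(g)) stop("unknown population: ", population)
  ac <- allele_counts(panel, population)
  keep <- !is.na(ac$m) & (1 - ac$m) >= maf_floor  # m is the major allele frequency
  empty <- tibble::tibble(population = character(0), chrom = character(0),
                          start_bp = integer(0), end_bp = integer(0),
                          n_markers = integer(0), span_bp = integer(0))
  out <- list()
  for (ch in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == ch & keep)
    K <- length(idx)
    if (K < min_markers) next
    pos <- panel$map$pos_bp[idx]
    strong <- matrix(0, K, K)
    inf <- matrix(0, K, K)
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        if (pos[j] - pos[i] > max_pair_bp) break
        pl <- dprime_ci(two_locus_em(g[, idx[i]], g[, idx[j]]))
        if (pl$class == "strong_LD") {
          strong[i, j] <- strong[j, i] <- 1
          inf[i, j] <- inf[j, i] <- 1
        } else if (pl$class == "recombination") {
          inf[i, j] <- inf[j, i] <- 1
        }
      }
    }
    Ps <- apply(apply(strong, 1, cumsum), 1, cumsum)  # 2D prefix sums
    Pi <- apply(apply(inf, 1, cumsum), 1, cumsum)
    rect <- function(P, i, j) {
      P[j, j] - (if (i > 1) P[i - 1, j] else 0) -
        (if (i > 1) P[j, i - 1] else 0) + (if (i > 1) P[i - 1, i - 1] else 0)
    }
    cand <- list()
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        if (pos[j] - pos[i] > max_pair_bp) break
        if (j - i + 1 < min_markers) next
        if (strong[i, j] != 1) next
        n_inf <- rect(Pi, i, j) / 2
        n_str <- rect(Ps, i, j) / 2
        if (n_inf > 0 && n_str / n_inf >= strong_fraction) {
          cand[[length(cand) + 1]] <- c(i, j)
        }
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    span <- pos[cand[, 2]] - pos[cand[, 1]]
    ord <- order(-span, cand[, 1])
    taken <- rep(FALSE, K)
    for (r in ord) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (any(taken[i:j])) next
      taken[i:j] <- TRUE
      out[[length(out) + 1]] <- tibble::tibble(
        population = population, chrom = ch,
        start_bp = pos[i], end_bp = pos[j],
        n_markers = j - i + 1L, span_bp = pos[j] - pos[i])
    }
  }
  if (!length(out)) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start_bp)
}

#' Keep only blocks larger than a span threshold
#'
#' @param blocks Output of [call_blocks()].
#' @param min_span_bp Strict lower bound on `span_bp` (default 5 Mb).
#' @return Filtered tibble, sorted by chromosome then start.
#' @export
filter_large_blocks <- function(blocks, min_span_bp = 5e6) {
  dplyr::arrange(blocks[blocks$span_bp > min_span_bp, , drop = FALSE],
                 .data$chrom, .data$start_bp)
}
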
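# small in-code fixtures shared across test files

make_map <- function(n = 4, chrom = "1", start = 100L, step = 100L) {
  tibble::tibble(marker_id = paste0("m", chrom, "_", seq_len(n)),
                 chrom = chrom,
                 pos_bp = as.integer(start + step * (seq_len(n) - 1)),
                 allele_ref = "A", allele_alt = "C")
}

# panel with two populations over one small chromosome
make_test_panel <- function(n_markers = 4, pops = c("popA", "popB"),
                            n_ind = 3, seed = 1) {
  set.seed(seed)
  map <- make_map(n_markers)
  geno <- lapply(pops, function(p) {
    g <- matrix(sample(0:2, n_ind * n_markers, replace = TRUE),
                nrow = n_ind,
                dimnames = list(paste0(p, "_", seq_len(n_ind)), NULL))
    g
  })
  names(geno) <- pops
  gt_panel(map, geno)
}

# a panel built from explicit dosage vectors (one population, one marker
# per list element is a column)
panel_from_calls <- function(calls, pop = "pop1", map = NULL) {
  g <- do.call(cbind, calls)
  if (is.null(map)) map <- make_map(ncol(g))
  rownames(g) <- paste0("i", seq_len(nrow(g)))
  gt_panel(map, stats::setNames(list(g), pop))
}

# brute-force two-sided Fisher p by enumerating all tables with the
# observed margins, using exact binomial coefficients (independent oracle)
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_; n <- r1 + r2
  lo <- max(0, k - r2); hi <- min(k, r1)
  prob <- vapply(lo:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, k - x) - lchoose(n, k))
  }, numeric(1))
  p_obs <- prob[a - lo + 1]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# windowed profile tibble built by hand from a per-marker hz vector
hz_tbl <- function(hz, chrom = "1", pop = NULL) {
  out <- tibble::tibble(chrom = chrom,
                        pos_bp = as.integer(100 * seq_along(hz)), hz = hz)
  if (!is.null(pop)) out$population <- pop
  out
}

# profiles for the 8-subgroup design: constant genome-wide windowed hz per
# subgroup, with the windows inside the test region overridden per subgroup;
# used to exercise the timeline rule table directly
constant_profiles <- function(region_levels, genome = 0.3, n_win = 20,
                              region_first = 5L, region_last = 12L) {
  purrr::map_dfr(names(region_levels), function(pop) {
    first <- seq_len(n_win)
    last <- first + 2L
    hz <- rep(genome, n_win)
    hz[first >= region_first & last <= region_last] <- region_levels[[pop]]
    tibble::tibble(population = pop, chrom = "1",
                   first = first, last = last,
                   start_bp = 100L * first, end_bp = 100L * last,
                   mid_bp = 100 * first + 100, hz_mean = hz)
  })
}

design_roles <- c("HWS40", "HWS50", "HWS53", "HWR9",
                  "LWS40", "LWS50", "LWS53", "LWR9")
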
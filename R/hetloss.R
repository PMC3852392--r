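#' Genome-wide mean heterozygosity change between two sampled populations
#'
#' Computes per-unit expected heterozygosity in both populations and the
#' mean change (later minus earlier; negative = loss). Units are either
#' single markers or nonoverlapping `W`-marker window means. The uncertainty
#' is the standard error of the mean computed over nonoverlapping `W`-marker
#' windows in both cases, which discounts the correlation of nearby markers
#' induced by linkage disequilibrium. Markers undefined (no calls) in either
#' population are excluded pairwise.
#'
#' @param panel A [gt_panel()] containing both populations.
#' @param earlier,later Population ids (e.g. the generation-40 and
#'   generation-53 samples of one line).
#' @param unit `"marker"` (default) or `"window"`.
#' @param cfg A [scan_config()] supplying the window size `W`.
#' @return One-row tibble: `pair`, `earlier`, `later`, `unit`, `mean_change`,
#'   `se`, `n_units`.
#' @export
mean_het_loss <- function(panel, earlier, later,
                          unit = c("marker", "window"), cfg = scan_config()) {
  unit <- match.arg(unit)
  ce <- allele_counts(panel, earlier)
  cl <- allele_counts(panel, later)
  ok <- !is.na(ce$hz) & !is.na(cl$hz)
  if (!any(ok)) stop("no marker with calls in both populations")
  d <- tibble::tibble(chrom = ce$chrom[ok], delta = cl$hz[ok] - ce$hz[ok])
  # nonoverlapping W-marker blocks per chromosome
  blocks <- unlist(lapply(split(seq_len(nrow(d)), d$chrom), function(idx) {
    ((seq_along(idx) - 1L) %/% cfg$W)
  }), use.names = FALSE)
  d$block <- paste(d$chrom, blocks)
  block_means <- tapply(d$delta, d$block, mean)
  if (unit == "marker") {
    mean_change <- mean(d$delta)
    n_units <- nrow(d)
  } else {
    mean_change <- mean(block_means)
    n_units <- length(block_means)
  }
  se <- if (length(block_means) > 1) {
    stats::sd(block_means) / sqrt(length(block_means))
  } else NA_real_
  tibble::tibble(pair = paste(earlier, "to", later),
                 earlier = earlier, later = later, unit = unit,
                 mean_change = mean_change, se = se,
                 n_units = as.integer(n_units))
}

#' Heterozygosity-loss table for several population pairs
#'
#' @param panel A [gt_panel()].
#' @param pairs Data frame or tibble with columns `earlier`, `later`.
#' @param ... Passed to [mean_het_loss()].
#' @return Tibble with one row per ordered pair.
#' @export
het_loss_table <- function(panel, pairs, ...) {
  purrr::pmap_dfr(pairs[c("earlier", "later")], function(earlier, later) {
    mean_het_loss(panel, earlier, later, ...)
  })
}
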
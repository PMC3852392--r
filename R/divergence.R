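#' Two-sided Fisher exact test for a 2x2 allele-count table
#'
#' Exact two-sided p-value by summing hypergeometric probabilities of all
#' tables with the observed margins whose probability is at most that of the
#' observed table (with relative tolerance 1e-7 for ties) — the standard
#' two-sided convention, matching `stats::fisher.test()`.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = populations,
#'   columns = alleles), or a length-4 vector `c(a, b, c, d)` filled by row.
#' @return List: `p` (two-sided p-value) and `degenerate` (`TRUE` when a row
#'   or column margin is zero, in which case `p = 1`).
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p  # 34/70
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(dim(tab) == c(2, 2), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1, degenerate = TRUE))
  }
  list(p = fisher_p2(a, a + b, c_, c_ + d), degenerate = FALSE)
}

# two-sided Fisher p for table rows (x1, n1-x1) / (x2, n2-x2), scalar
fisher_p2 <- function(x1, n1, x2, n2) {
  K <- x1 + x2                    # total "allele 1"
  N <- n1 + n2
  lo <- max(0, K - n2)
  hi <- min(K, n1)
  supp <- lo:hi
  d <- stats::dhyper(supp, K, N - K, n1)
  p_obs <- d[match(x1, supp)]
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

# vectorised over markers, computing each unique margin/count combo once
fisher_p2_vec <- function(x1, n1, x2, n2) {
  key <- paste(x1, n1, x2, n2)
  u <- !duplicated(key)
  pu <- mapply(fisher_p2, x1[u], n1[u], x2[u], n2[u])
  unname(pu[match(key, key[u])])
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests, >= 1.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_cut(0.05, 55983)  # 8.93e-7
#' @export
bonferroni_cut <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Genome-wide Fisher exact divergence scan between two populations
#'
#' Tests every marker with at least one successful call in both populations
#' for a difference in allele frequency, against a Bonferroni cut of
#' `alpha / n_tests` where `n_tests` is the number of markers actually
#' tested. Markers monomorphic for the same allele in both populations give
#' `p = 1` and are counted in `n_tests`.
#'
#' @param panel A [gt_panel()] containing both populations.
#' @param pop_a,pop_b Population ids.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble of class `divergence_scan` with columns `marker_id`,
#'   `chrom`, `pos_bp`, `p_value`, `significant`; attributes `n_tests`,
#'   `threshold`, `pair`.
#' @export
scan_pair <- function(panel, pop_a, pop_b, alpha = 0.05) {
  ca <- allele_counts(panel, pop_a)
  cb <- allele_counts(panel, pop_b)
  testable <- ca$n_total > 0 & cb$n_total > 0
  if (!any(testable)) stop("no testable markers (no marker called in both populations)")
  p <- rep(NA_real_, nrow(ca))
  p[testable] <- fisher_p2_vec(ca$n_alt[testable], ca$n_total[testable],
                               cb$n_alt[testable], cb$n_total[testable])
  thr <- bonferroni_cut(alpha, sum(testable))
  out <- tibble::tibble(marker_id = ca$marker_id, chrom = ca$chrom,
                        pos_bp = ca$pos_bp, p_value = p,
                        significant = !is.na(p) & p < thr)
  attr(out, "n_tests") <- sum(testable)
  attr(out, "threshold") <- thr
  attr(out, "pair") <- c(pop_a, pop_b)
  class(out) <- c("divergence_scan", class(out))
  out
}

#' Ordered -log p regression between two divergence scans
#'
#' Sorts the -log10 p-values of each scan from largest to smallest, pairs
#' them rank-for-rank, and fits an ordinary least-squares regression of the
#' `y` scan's ordered values on the `x` scan's. A slope above 1 means the
#' `y` pair's p-values are globally lower (more divergence) than the `x`
#' pair's.
#'
#' @param scan_x,scan_y [scan_pair()] results over the same number of
#'   markers.
#' @param base Logarithm base for -log p (default 10).
#' @param intercept Fit an intercept (default `TRUE`).
#' @return Object of class `ordered_logp_fit`: list with `slope`, `stderr`,
#'   `n`, `intercept`, `base` and the underlying `lm` fit. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
ordered_logp_regression <- function(scan_x, scan_y, base = 10, intercept = TRUE) {
  px <- scan_x$p_value[!is.na(scan_x$p_value)]
  py <- scan_y$p_value[!is.na(scan_y$p_value)]
  if (length(px) != length(py)) {
    stop("scans cover different numbers of tested markers (",
         length(px), " vs ", length(py), ")")
  }
  x <- sort(-log(px, base = base), decreasing = TRUE)
  y <- sort(-log(py, base = base), decreasing = TRUE)
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  co <- suppressWarnings(summary(fit))$coefficients  # exact fits are legal
  structure(list(slope = unname(co["x", "Estimate"]),
                 stderr = unname(co["x", "Std. Error"]),
                 n = length(x), intercept = intercept, base = base,
                 fit = fit),
            class = "ordered_logp_fit")
}

#' @export
print.ordered_logp_fit <- function(x, ...) {
  cat("<ordered_logp_fit> slope ", signif(x$slope, 4), " (SE ",
      signif(x$stderr, 4), ") over ", x$n, " ordered -log p pairs\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.ordered_logp_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                 std.error = co[, "Std. Error"],
                 statistic = co[, "t value"], p.value = co[, "Pr(>|t|)"])
}

#' @exportS3Method generics::glance
glance.ordered_logp_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(slope = x$slope, std.error = x$stderr,
                 r.squared = s$r.squared, n = x$n, base = x$base,
                 intercept = x$intercept)
}

#' @exportS3Method generics::glance
glance.divergence_scan <- function(x, ...) {
  tibble::tibble(pop_a = attr(x, "pair")[1], pop_b = attr(x, "pair")[2],
                 n_tests = attr(x, "n_tests"),
                 threshold = attr(x, "threshold"),
                 n_significant = sum(x$significant, na.rm = TRUE))
}
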
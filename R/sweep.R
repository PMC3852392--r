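#' Expected heterozygosity of a biallelic marker
#'
#' `Hz = 1 - (m^2 + (1 - m)^2) = 2 m (1 - m)` where `m` is the major allele
#' frequency. The function is symmetric in `m` and `1 - m`, so either the
#' major or the minor allele frequency can be supplied. `NA` passes through
#' (markers with no successful calls).
#'
#' @param m Allele frequency, in \[0, 1\] (vectorised).
#' @return Expected heterozygosity in \[0, 0.5\].
#' @examples
#' marker_het(c(0.5, 0.8, 1))  # 0.5, 0.32, 0
#' @export
marker_het <- function(m) {
  if (any(!is.na(m) & (m < 0 | m > 1))) {
    stop("allele frequency outside [0, 1]")
  }
  2 * m * (1 - m)
}

#' Configuration for the windowed heterozygosity scan
#'
#' @param W Window size in markers (default 100, the size matching the
#'   observed wavelength of heterozygosity fluctuations along a dense SNP
#'   map).
#' @param step Windows advance by this many markers (default 1, fully
#'   sliding). Must satisfy `1 <= step <= W`.
#' @param alpha Family-wise two-sided error rate for the empirical drift
#'   null (default 0.05).
#' @param fixation_threshold Windowed `Hz` below which a region counts as
#'   fixed in a population (default 0.03: with 20 sampled diploids a truly
#'   fixed region still reads nonzero windowed `Hz` — a single stray
#'   heterozygote puts a marker at `Hz ~ 0.05` — and flagged regions carry
#'   partially swept shoulder windows).
#' @param reduced_threshold Windowed `Hz` below which a region counts as
#'   reduced-but-not-fixed. Default `NULL` = half the population's
#'   genome-wide median windowed `Hz`, computed at classification time.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(W = 100, step = 1, alpha = 0.05,
                        fixation_threshold = 0.03, reduced_threshold = NULL) {
  stopifnot(W >= 1, step >= 1, step <= W, alpha > 0, alpha < 1,
            fixation_threshold > 0)
  if (!is.null(reduced_threshold) && reduced_threshold <= fixation_threshold) {
    stop("reduced_threshold must exceed fixation_threshold")
  }
  structure(list(W = as.integer(W), step = as.integer(step), alpha = alpha,
                 fixation_threshold = fixation_threshold,
                 reduced_threshold = reduced_threshold),
            class = "scan_config")
}

# rolling mean of W consecutive values advancing by `step`, NAs excluded
# from the mean with the divisor reduced accordingly
roll_mean_na <- function(x, W, step) {
  n <- length(x)
  if (n < W) return(list(mean = numeric(0), first = integer(0)))
  v <- ifelse(is.na(x), 0, x)
  cnt <- as.integer(!is.na(x))
  cs <- c(0, cumsum(v))
  cc <- c(0, cumsum(cnt))
  first <- seq.int(1L, n - W + 1L, by = step)
  last <- first + W - 1L
  s <- cs[last + 1L] - cs[first]
  k <- cc[last + 1L] - cc[first]
  list(mean = ifelse(k > 0, s / k, NA_real_), first = first)
}

#' Windowed moving-average heterozygosity profile
#'
#' Averages per-marker expected heterozygosity over windows of `W`
#' consecutive markers, per chromosome (windows never span a chromosome
#' boundary), advancing by `cfg$step` markers. Markers with undefined `Hz`
#' (no calls) are excluded from the window mean with the divisor reduced.
#' Chromosomes with fewer than `W` markers are skipped with a warning.
#'
#' @param het Tibble with columns `chrom`, `pos_bp`, `hz` and optionally
#'   `population` / `marker_id` — e.g. the output of [allele_counts()].
#' @param cfg A [scan_config()].
#' @return Tibble with one row per window: `population` (if present in the
#'   input), `chrom`, `first` and `last` (marker indices within the
#'   chromosome), `start_bp`, `end_bp`, `mid_bp`, `hz_mean`.
#' @export
window_profile <- function(het, cfg = scan_config()) {
  het <- tibble::as_tibble(het)
  stopifnot(all(c("chrom", "pos_bp", "hz") %in% names(het)))
  by_pop <- if ("population" %in% names(het)) split(het, het$population) else list(het)
  purrr::map_dfr(by_pop, function(h) {
    h <- h[order(match(h$chrom, unique(h$chrom)), h$pos_bp), ]
    purrr::map_dfr(split(h, factor(h$chrom, levels = unique(h$chrom))), function(hc) {
      if (nrow(hc) < cfg$W) {
        warning("chromosome ", hc$chrom[1], " has fewer than W = ", cfg$W,
                " markers; skipped", call. = FALSE)
        return(NULL)
      }
      r <- roll_mean_na(hc$hz, cfg$W, cfg$step)
      last <- r$first + cfg$W - 1L
      tibble::tibble(
        population = if ("population" %in% names(hc)) hc$population[1] else NA_character_,
        chrom = hc$chrom[1],
        first = r$first, last = last,
        start_bp = hc$pos_bp[r$first], end_bp = hc$pos_bp[last],
        mid_bp = (hc$pos_bp[r$first] + hc$pos_bp[last]) / 2,
        hz_mean = r$mean)
    })
  })
}

#' Windowed heterozygosity profiles for every population in a panel
#'
#' @param panel A [gt_panel()].
#' @param cfg A [scan_config()].
#' @param population Population ids; default all.
#' @return Tibble as in [window_profile()], stacked over populations.
#' @export
het_profiles <- function(panel, cfg = scan_config(),
                         population = populations(panel)) {
  window_profile(allele_counts(panel, population), cfg)
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !all(a$chrom == b$chrom) || !all(a$first == b$first) ||
      !all(a$start_bp == b$start_bp)) {
    stop("profiles were not computed on the same window grid")
  }
}

#' Difference between two heterozygosity profiles
#'
#' Per-window `hz_mean(a) - hz_mean(b)`, sign preserved. Both profiles must
#' be on the identical window grid (same map, `W`, `step`).
#'
#' @param a,b Single-population profiles from [window_profile()].
#' @return Tibble with the window grid columns and `diff`.
#' @export
profile_difference <- function(a, b) {
  check_same_grid(a, b)
  out <- a[c("chrom", "first", "last", "start_bp", "end_bp", "mid_bp")]
  out$diff <- a$hz_mean - b$hz_mean
  out
}

#' Change between two profile differences over time
#'
#' Per-window `diff(t2) - diff(t1)`: how much the between-line heterozygosity
#' contrast moved over the interval, the quantity screened against the
#' empirical drift null.
#'
#' @param diff_t1,diff_t2 Outputs of [profile_difference()] on the same grid.
#' @return Tibble with the window grid columns and `change`.
#' @export
profile_change <- function(diff_t1, diff_t2) {
  check_same_grid(diff_t1, diff_t2)
  out <- diff_t1[c("chrom", "first", "last", "start_bp", "end_bp", "mid_bp")]
  out$change <- diff_t2$diff - diff_t1$diff
  out
}

#' Empirical drift-null significance cuts for a change profile
#'
#' Fits a normal distribution to the observed genome-wide window-wise change
#' distribution (assumed drift-dominated) and returns two-sided cuts at the
#' family-wise level `cfg$alpha`, Bonferroni-corrected for the number of
#' nonoverlapping `W`-marker windows needed to cover the genome:
#' `n_indep = ceiling(n_markers / W)`, per-tail probability
#' `q = (alpha / 2) / n_indep`, cuts `mu + sigma * qnorm(c(q, 1 - q))`.
#'
#' @param change Numeric vector of window changes (or a tibble from
#'   [profile_change()], whose `change` column is used).
#' @param cfg A [scan_config()].
#' @param n_markers Total markers covering the genome (Bonferroni basis).
#' @return List of class `sweep_threshold`: `lower`, `upper`, `mu`, `sigma`,
#'   `q`, `n_indep`.
#' @export
empirical_threshold <- function(change, cfg = scan_config(), n_markers) {
  if (is.data.frame(change)) change <- change$change
  change <- change[!is.na(change)]
  stopifnot(length(change) > 0, n_markers > 0)
  n_indep <- ceiling(n_markers / cfg$W)
  q <- (cfg$alpha / 2) / n_indep
  mu <- mean(change)
  sigma <- stats::sd(change)
  if (!is.finite(sigma) || sigma == 0) stop("degenerate null: sd of changes is zero")
  structure(list(lower = mu + sigma * stats::qnorm(q),
                 upper = mu + sigma * stats::qnorm(1 - q),
                 mu = mu, sigma = sigma, q = q, n_indep = as.integer(n_indep)),
            class = "sweep_threshold")
}

#' @export
print.sweep_threshold <- function(x, ...) {
  cat("<sweep_threshold> cuts [", signif(x$lower, 4), ", ", signif(x$upper, 4),
      "]  (q = ", signif(x$q, 4), " per tail, ", x$n_indep,
      " independent windows)\n", sep = "")
  invisible(x)
}

#' Call significant sweep regions from a change profile
#'
#' Windows strictly below the lower cut or strictly above the upper cut are
#' flagged; runs of consecutive (overlapping or adjacent by one step)
#' flagged windows of the same sign on one chromosome are merged into one
#' region spanning the first window's first marker to the last window's last
#' marker. Ties at exactly the cut are not flagged.
#'
#' @param change Tibble from [profile_change()].
#' @param cuts A `sweep_threshold` from [empirical_threshold()], or a
#'   numeric `c(lower, upper)`.
#' @return Tibble of regions: `chrom`, `start_bp`, `end_bp`, `direction`
#'   (`"loss"` below the lower cut, `"gain"` above the upper), `peak`
#'   (change of largest magnitude), `n_windows`, `first`, `last` (marker
#'   index span).
#' @export
call_regions <- function(change, cuts) {
  if (inherits(cuts, "sweep_threshold")) cuts <- c(cuts$lower, cuts$upper)
  stopifnot(length(cuts) == 2, cuts[1] <= cuts[2])
  flag <- dplyr::case_when(change$change < cuts[1] ~ -1L,
                           change$change > cuts[2] ~ 1L,
                           TRUE ~ 0L)
  keep <- which(flag != 0L)
  if (!length(keep)) {
    return(tibble::tibble(chrom = character(0), start_bp = integer(0),
                          end_bp = integer(0), direction = character(0),
                          peak = numeric(0), n_windows = integer(0),
                          first = integer(0), last = integer(0)))
  }
  d <- change[keep, ]
  d$sign <- flag[keep]
  # new run when chromosome or sign changes, or the next flagged window
  # neither overlaps nor immediately follows the previous one (flagged
  # windows sharing markers must merge so regions never overlap)
  step <- if (nrow(change) >= 2) {
    s <- diff(change$first[change$chrom == change$chrom[1]])
    if (length(s)) min(s) else 1L
  } else 1L
  n <- nrow(d)
  brk <- c(TRUE, d$chrom[-1] != d$chrom[-n] |
             d$sign[-1] != d$sign[-n] |
             d$first[-1] > pmax(d$last[-n], d$first[-n] + step))
  d$run <- cumsum(brk)
  dplyr::group_by(d, .data$run) |>
    dplyr::summarise(chrom = .data$chrom[1],
                     start_bp = min(.data$start_bp),
                     end_bp = max(.data$end_bp),
                     direction = if (.data$sign[1] < 0) "loss" else "gain",
                     peak = .data$change[which.max(abs(.data$change))],
                     n_windows = dplyr::n(),
                     first = min(.data$first),
                     last = max(.data$last),
                     .groups = "drop") |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$chrom, .data$start_bp)
}

region_state <- function(hz, fixation_threshold, reduced_threshold) {
  dplyr::case_when(hz < fixation_threshold ~ "fixed",
                   hz < reduced_threshold ~ "reduced",
                   TRUE ~ "polymorphic")
}

#' Date a sweep region from the fixation pattern across subgroups
#'
#' Given windowed heterozygosity profiles for the eight subgroups of the
#' two-line design (selected lines sampled at generations 40, 50 and 53;
#' relaxed lines split off at generation 45 and sampled at their generation
#' 9), classifies the region in each subgroup as fixed, reduced or
#' polymorphic from the region-mean windowed `Hz`, and applies the timeline
#' rule table:
#'
#' * (a) fixed in both lines already at generation 40 — shared event, onset
#'   before 40;
#' * (b) polymorphic at 40, fixed at 50 and 53, fixed in the relaxed line —
#'   onset in (40, 45\], fixation in (40, 50\] (it may predate the split);
#' * (c) polymorphic at 40, fixed at 50 and 53, reduced but not fixed in the
#'   relaxed line — onset in (40, 45\], fixation in (45, 50\];
#' * (d) polymorphic at 40 and 50, fixed at 53 only — onset in (45, 53\],
#'   fixation in (50, 53\];
#' * (e) anything else — not fixed; the per-subgroup states are attached.
#'
#' @param region One region (single row of [call_regions()] output, or any
#'   list/row with `chrom`, `first`, `last`).
#' @param profiles Profiles from [het_profiles()] for all eight subgroups,
#'   on the shared window grid.
#' @param roles Named character vector mapping the eight design roles
#'   (`HWS40`, `HWS50`, `HWS53`, `HWR9`, `LWS40`, `LWS50`, `LWS53`, `LWR9`)
#'   to population ids in `profiles`. Default: roles equal population ids.
#' @param cfg A [scan_config()] supplying `fixation_threshold` and
#'   `reduced_threshold` (default for the latter: half that population's
#'   genome-wide median windowed `Hz`).
#' @return One-row tibble: `rule` (`"a"`..`"e"`), `lineage` (`"HW"`, `"LW"`,
#'   `"both"`, `"pre-divergence"` or `NA`), `onset_lo`, `onset_hi`,
#'   `fixation_lo`, `fixation_hi` (generation interval bounds, `(lo, hi]`;
#'   `NA` when not fixed), and `states` (per-subgroup states as
#'   `"role=state"` strings, collapsed).
#' @export
classify_timeline <- function(region, profiles, roles = NULL,
                              cfg = scan_config()) {
  need <- c("HWS40", "HWS50", "HWS53", "HWR9", "LWS40", "LWS50", "LWS53", "LWR9")
  if (is.null(roles)) roles <- stats::setNames(need, need)
  if (!all(need %in% names(roles))) {
    stop("roles must name all eight subgroups: ", paste(need, collapse = ", "))
  }
  st <- vapply(need, function(role) {
    pop <- roles[[role]]
    pr <- profiles[profiles$population == pop & profiles$chrom == region$chrom, ]
    # contributing windows only: fully inside the region span (the span is
    # padded by up to W markers beyond the flagged run on each side)
    win <- pr[pr$first >= region$first & pr$last <= region$last, ]
    if (!nrow(pr) || !nrow(win)) {
      stop("region windows absent from profile of subgroup ", role)
    }
    red <- cfg$reduced_threshold
    if (is.null(red)) {
      red <- stats::median(profiles$hz_mean[profiles$population == pop],
                           na.rm = TRUE) / 2
    }
    region_state(mean(win$hz_mean, na.rm = TRUE), cfg$fixation_threshold, red)
  }, character(1))

  states <- paste(need, st[need], sep = "=", collapse = "; ")
  res <- function(rule, lineage, o_lo, o_hi, f_lo, f_hi) {
    tibble::tibble(rule = rule, lineage = lineage,
                   onset_lo = o_lo, onset_hi = o_hi,
                   fixation_lo = f_lo, fixation_hi = f_hi, states = states)
  }
  if (st["HWS40"] == "fixed" && st["LWS40"] == "fixed") {
    return(res("a", "both", -Inf, 40, -Inf, 40))
  }
  per_lineage <- function(X) {
    s40 <- st[paste0(X, "WS40")]; s50 <- st[paste0(X, "WS50")]
    s53 <- st[paste0(X, "WS53")]; sR <- st[paste0(X, "WR9")]
    if (s40 == "polymorphic" && s50 == "fixed" && s53 == "fixed") {
      if (sR == "fixed")   return(list(rule = "b", o = c(40, 45), f = c(40, 50)))
      if (sR == "reduced") return(list(rule = "c", o = c(40, 45), f = c(45, 50)))
    }
    if (s40 == "polymorphic" && s50 == "polymorphic" && s53 == "fixed") {
      return(list(rule = "d", o = c(45, 53), f = c(50, 53)))
    }
    NULL
  }
  hw <- per_lineage("H"); lw <- per_lineage("L")
  if (!is.null(hw) && !is.null(lw)) {
    pick <- if (hw$o[1] <= lw$o[1]) hw else lw
    return(res(pick$rule, "both", pick$o[1], pick$o[2], pick$f[1], pick$f[2]))
  }
  if (!is.null(hw)) return(res(hw$rule, "HW", hw$o[1], hw$o[2], hw$f[1], hw$f[2]))
  if (!is.null(lw)) return(res(lw$rule, "LW", lw$o[1], lw$o[2], lw$f[1], lw$f[2]))
  res("e", NA_character_, NA_real_, NA_real_, NA_real_, NA_real_)
}

#' Export regions or blocks as BED
#'
#' Internal coordinates are 1-based inclusive; BED is written 0-based
#' half-open.
#'
#' @param x Tibble with `chrom`, `start_bp`, `end_bp` (regions or haplotype
#'   blocks).
#' @param path Output file.
#' @param names Optional name column values.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path, names = NULL) {
  bed <- data.frame(x$chrom, x$start_bp - 1L, x$end_bp,
                    if (is.null(names)) "." else names)
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
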
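#' Run the full sweep-detection and dating analysis
#'
#' Orchestrates the stages of the two-line genome scan: missingness QC,
#' windowed heterozygosity profiles for all subgroups, the between-line
#' profile differences at the first and last sampled generations and their
#' change, the empirical drift-null threshold, significant-region calling,
#' timeline classification of each region, Fisher exact divergence scans of
#' each relaxed line against its ancestral selected line with the ordered
#' -log p regression, and the heterozygosity-loss table. Haplotype-block
#' calling is available as an optional stage (it is quadratic in markers per
#' chromosome and meant for targeted panels).
#'
#' @param panel A [gt_panel()] holding all subgroup samples.
#' @param roles Named character vector mapping the design roles `HWS40`,
#'   `HWS50`, `HWS53`, `HWR9`, `LWS40`, `LWS50`, `LWS53`, `LWR9` to
#'   population ids in `panel`. Default: identity for the roles present.
#' @param cfg A [scan_config()].
#' @param alpha_marker Family-wise error rate for the marker-wise Fisher
#'   scans (default 0.05).
#' @param stages Which stages to run; any subset of `"qc"`, `"scan"`,
#'   `"divergence"`, `"hetloss"`, `"blocks"`.
#' @param max_missing QC missingness cut (markers with at least this many
#'   missing calls pooled over all populations are dropped).
#' @param block_pops Populations for the optional blocks stage.
#' @param out_dir If non-`NULL`, exports are written here (TSV profiles and
#'   tables, BED regions, JSON summary).
#' @return A list with elements (per executed stage): `panel`, `removed`,
#'   `profiles`, `diff40`, `diff53`, `change`, `threshold`, `regions`
#'   (including timeline columns when all eight subgroups are present),
#'   `scans`, `logp_fit`, `hetloss`, `blocks`, `summary`.
#' @export
run_full_analysis <- function(panel, roles = NULL, cfg = scan_config(),
                              alpha_marker = 0.05,
                              stages = c("qc", "scan", "divergence", "hetloss"),
                              max_missing = 10,
                              block_pops = c("HWS40", "LWS40"),
                              out_dir = NULL) {
  all_roles <- c("HWS40", "HWS50", "HWS53", "HWR9",
                 "LWS40", "LWS50", "LWS53", "LWR9")
  if (is.null(roles)) {
    roles <- stats::setNames(intersect(all_roles, populations(panel)),
                             intersect(all_roles, populations(panel)))
  }
  if (anyDuplicated(roles)) stop("a population is assigned to two roles")
  res <- list()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if ("qc" %in% stages) {
    q <- qc_filter_missing(panel, max_missing)
    panel <- q$panel
    res$removed <- q$removed
  }
  res$panel <- panel
  n_markers <- nrow(panel$map)

  if ("scan" %in% stages) {
    need <- c("HWS40", "LWS40", "HWS53", "LWS53")
    miss <- setdiff(need, names(roles))
    if (length(miss)) stop("scan stage needs roles: ", paste(miss, collapse = ", "))
    res$profiles <- het_profiles(panel, cfg, population = unname(roles))
    prof_of <- function(role) {
      res$profiles[res$profiles$population == roles[[role]], ]
    }
    res$diff40 <- profile_difference(prof_of("HWS40"), prof_of("LWS40"))
    res$diff53 <- profile_difference(prof_of("HWS53"), prof_of("LWS53"))
    res$change <- profile_change(res$diff40, res$diff53)
    res$threshold <- empirical_threshold(res$change, cfg, n_markers)
    regions <- call_regions(res$change, res$threshold)
    if (nrow(regions) && all(all_roles %in% names(roles))) {
      tl <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
        classify_timeline(regions[i, ], res$profiles, roles, cfg)
      })
      regions <- dplyr::bind_cols(regions, tl)
    }
    res$regions <- regions
  }

  if ("divergence" %in% stages) {
    res$scans <- list()
    if (all(c("HWS40", "HWR9") %in% names(roles))) {
      res$scans$HW <- scan_pair(panel, roles[["HWS40"]], roles[["HWR9"]],
                                alpha_marker)
    }
    if (all(c("LWS40", "LWR9") %in% names(roles))) {
      res$scans$LW <- scan_pair(panel, roles[["LWS40"]], roles[["LWR9"]],
                                alpha_marker)
    }
    if (!length(res$scans)) {
      stop("divergence stage needs roles HWS40+HWR9 and/or LWS40+LWR9")
    }
    if (length(res$scans) == 2) {
      res$logp_fit <- ordered_logp_regression(res$scans$HW, res$scans$LW)
    }
  }

  if ("hetloss" %in% stages) {
    pairs <- tibble::tibble(
      earlier = c("HWS40", "HWS40", "LWS40", "LWS40"),
      later = c("HWS53", "HWR9", "LWS53", "LWR9"))
    pairs <- pairs[pairs$earlier %in% names(roles) & pairs$later %in% names(roles), ]
    if (nrow(pairs)) {
      pairs$earlier <- unname(roles[pairs$earlier])
      pairs$later <- unname(roles[pairs$later])
      res$hetloss <- het_loss_table(panel, pairs, cfg = cfg)
    }
  }

  if ("blocks" %in% stages) {
    res$blocks <- purrr::map_dfr(intersect(block_pops, names(roles)),
                                 function(role) {
                                   call_blocks(panel, roles[[role]])
                                 })
  }

  res$summary <- analysis_summary(res, cfg, alpha_marker, n_markers)
  if (!is.null(out_dir)) write_outputs(res, out_dir)
  res
}

analysis_summary <- function(res, cfg, alpha_marker, n_markers) {
  s <- list(n_markers = n_markers,
            n_removed_qc = length(res$removed),
            W = cfg$W, alpha = cfg$alpha)
  if (!is.null(res$threshold)) {
    s$threshold_lower <- res$threshold$lower
    s$threshold_upper <- res$threshold$upper
    s$n_independent_windows <- res$threshold$n_indep
    s$n_regions <- nrow(res$regions)
    if ("rule" %in% names(res$regions)) {
      s$timeline_rules <- as.list(table(res$regions$rule))
    }
  }
  if (!is.null(res$scans)) {
    s$divergence <- lapply(res$scans, function(x) as.list(glance(x)))
  }
  if (!is.null(res$logp_fit)) {
    s$ordered_logp_slope <- res$logp_fit$slope
    s$ordered_logp_se <- res$logp_fit$stderr
  }
  if (!is.null(res$hetloss)) {
    s$hetloss <- stats::setNames(as.list(res$hetloss$mean_change),
                                 res$hetloss$pair)
  }
  if (!is.null(res$blocks)) s$n_blocks <- nrow(res$blocks)
  s
}

write_outputs <- function(res, out_dir) {
  p <- function(f) file.path(out_dir, f)
  if (!is.null(res$profiles)) readr::write_tsv(res$profiles, p("profiles.tsv"))
  if (!is.null(res$change)) readr::write_tsv(res$change, p("change.tsv"))
  if (!is.null(res$regions)) {
    readr::write_tsv(res$regions, p("regions.tsv"))
    if (nrow(res$regions)) {
      write_bed(res$regions, p("regions.bed"), names = res$regions$direction)
    }
  }
  if (!is.null(res$scans)) {
    for (nm in names(res$scans)) {
      readr::write_tsv(res$scans[[nm]], p(paste0("divergence_", nm, ".tsv")))
    }
  }
  if (!is.null(res$hetloss)) readr::write_tsv(res$hetloss, p("hetloss.tsv"))
  if (!is.null(res$blocks)) {
    readr::write_tsv(res$blocks, p("blocks.tsv"))
    if (nrow(res$blocks)) {
      write_bed(res$blocks, p("blocks.bed"), names = res$blocks$population)
    }
  }
  jsonlite::write_json(res$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
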
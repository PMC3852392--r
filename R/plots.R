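#' Plot windowed heterozygosity profiles
#'
#' One line per population along the genome, faceted by chromosome.
#'
#' @param profiles Output of [het_profiles()] / [window_profile()].
#' @return A ggplot object.
#' @export
plot_het_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$mid_bp / 1e6, y = .data$hz_mean,
                               colour = .data$population)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "windowed heterozygosity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a change profile with its significance cuts and called regions
#'
#' @param change Output of [profile_change()].
#' @param cuts A `sweep_threshold` from [empirical_threshold()] (optional).
#' @param regions Output of [call_regions()] (optional).
#' @return A ggplot object.
#' @export
plot_change_profile <- function(change, cuts = NULL, regions = NULL) {
  g <- ggplot2::ggplot(change,
                       ggplot2::aes(x = .data$mid_bp / 1e6, y = .data$change)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "change in Hz difference") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions)) {
    g <- g + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.2)
  }
  if (!is.null(cuts)) {
    g <- g + ggplot2::geom_hline(yintercept = c(cuts$lower, cuts$upper),
                                 linetype = "dashed", colour = "blue")
  }
  g
}

#' Genome-wide -log10 p profile of a divergence scan
#'
#' @param object A `divergence_scan` from [scan_pair()].
#' @param ... Unused.
#' @return A ggplot object with the Bonferroni cut as a dashed line.
#' @exportS3Method ggplot2::autoplot
autoplot.divergence_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object[!is.na(object$p_value), ],
                  ggplot2::aes(x = .data$pos_bp / 1e6,
                               y = -log10(.data$p_value))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
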
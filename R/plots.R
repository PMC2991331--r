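#' Plot a border or peak alignment profile
#'
#' Line plot of a profile tibble (`rel_bp`/`value` or
#' `distance_bp`/`value`, optionally with a `stratum` column) as produced
#' by [value_profile()], [peak_density_profile()], [coverage_profile()] or
#' [delta_vs_peak_distance()].
#'
#' @param profile profile tibble.
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plot_profile <- function(profile, ylab = "value") {
  xcol <- if ("rel_bp" %in% names(profile)) "rel_bp" else "distance_bp"
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data[[xcol]] / 1000, y = .data$value))
  p <- if ("stratum" %in% names(profile)) {
    p + ggplot2::geom_line(ggplot2::aes(color = .data$stratum))
  } else {
    p + ggplot2::geom_line(color = "#2166ac")
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = if (xcol == "rel_bp") {
      "position relative to border (kb; positive = inside)"
    } else "distance to nearest peak (kb)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a probe track with called domains
#'
#' @param track single-value probe-track tibble.
#' @param lads optional LAD interval tibble drawn as shaded rectangles.
#' @param chrom chromosome to plot (default: first in the track).
#' @param smooth_window optional running-median window applied before
#'   plotting (e.g. 15 probes).
#' @return a ggplot object.
#' @export
plot_track <- function(track, lads = NULL, chrom = NULL, smooth_window = NULL) {
  vals <- assert_track(track)
  chrom <- chrom %||% track$chrom[1]
  tr <- track[track$chrom == chrom, ]
  if (!is.null(smooth_window)) tr <- smooth_track(tr, smooth_window, "median")
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                        y = .data[[vals[1]]]))
  if (!is.null(lads)) {
    ld <- lads[lads$chrom == chrom, ]
    if (nrow(ld) > 0) {
      p <- p + ggplot2::geom_rect(
        data = ld,
        ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
        ymin = -Inf, ymax = Inf, fill = "#fddbc7", alpha = 0.6,
        inherit.aes = FALSE)
    }
  }
  p +
    ggplot2::geom_line(linewidth = 0.3, color = "grey20") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom),
                  y = "log2(Dam-fusion / Dam-only)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a permutation enrichment result
#'
#' Histogram of the permuted fractions with the observed fraction marked.
#'
#' @param object a `lads_enrichment` object.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.lads_enrichment <- function(object, ...) {
  df <- tibble(fraction = object$permuted_fractions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed_fraction,
                        color = "#b2182b", linewidth = 1) +
    ggplot2::labs(x = "fraction of peaks in regions (permutation null)",
                  y = "permutations",
                  title = sprintf("observed %.1f%% vs expected %.1f%% (%s p = %.4g)",
                                  100 * object$observed_fraction,
                                  100 * object$expected_fraction,
                                  object$direction, object$p_value)) +
    ggplot2::theme_minimal()
}
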
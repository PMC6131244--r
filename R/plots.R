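#' Plot a cohort AI count track along a chromosome
#'
#' Step profile of tumor counts (raw and, when present, max-smoothed) with
#' optional peak apex annotations -- the per-chromosome recurrence profile
#' view.
#'
#' @param track Count track tibble (optionally with `smoothed`).
#' @param chrom Chromosome to draw.
#' @param peaks Optional peak tibble; apexes on `chrom` are shaded.
#' @return A ggplot object.
#' @export
plot_count_track <- function(track, chrom, peaks = NULL) {
  tr <- track[track$chrom == chrom, ]
  p <- ggplot2::ggplot(tr) +
    ggplot2::geom_step(ggplot2::aes(x = .data$start / 1e6, y = .data$value),
                       color = "grey40") +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom),
                  y = "tumors with AI",
                  title = sprintf("AI recurrence on %s", chrom)) +
    ggplot2::theme_minimal()
  if ("smoothed" %in% names(tr)) {
    p <- p + ggplot2::geom_step(
      ggplot2::aes(x = .data$start / 1e6, y = .data$smoothed),
      color = "steelblue")
  }
  if (!is.null(peaks)) {
    pk <- peaks[peaks$chrom == chrom, ]
    if (nrow(pk) > 0) {
      p <- p + ggplot2::geom_rect(
        data = pk,
        ggplot2::aes(xmin = .data$apex_start / 1e6,
                     xmax = .data$apex_end / 1e6,
                     ymin = -Inf, ymax = Inf),
        fill = "firebrick", alpha = 0.15)
    }
  }
  p
}

#' Plot SNV density against segment LRR
#'
#' One point per AI segment; the lowess curve is the visual guide for the
#' rise of mutation density with copy number.
#'
#' @param density Tibble from [snv_density_per_segment()].
#' @param frac Lowess span.
#' @return A ggplot object.
#' @export
plot_snv_density <- function(density, frac = 0.3) {
  curve <- lowess_curve(density$mean_lrr, density$density, frac = frac)
  ggplot2::ggplot(density,
                  ggplot2::aes(x = .data$mean_lrr, y = .data$density)) +
    ggplot2::geom_point(alpha = 0.3, color = "darkgreen") +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$x, y = .data$fitted),
                       color = "blue", linewidth = 1) +
    ggplot2::labs(x = "segment mean LRR", y = "SNVs per callable Mb") +
    ggplot2::theme_minimal()
}

#' Plot the gain/loss co-occurrence odds-ratio matrix
#'
#' Heatmap of log2 odds ratios over (gain locus, loss locus) grid pairs of
#' one chromosome.
#'
#' @param scan Result of [cooccurrence_or_scan()].
#' @return A ggplot object.
#' @export
plot_cooccurrence <- function(scan) {
  ggplot2::ggplot(scan$grid,
                  ggplot2::aes(x = .data$x / 1e6, y = .data$y / 1e6,
                               fill = .data$log2_or)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::labs(x = "gain locus (Mb)", y = "loss locus (Mb)",
                  fill = "log2 OR") +
    ggplot2::theme_minimal()
}
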
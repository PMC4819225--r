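# Quick-look ggplot2 figures for the main result types.

#' Plot a smoothed ratio track
#'
#' Log2(e4C/control) along one chromosome with the hit cut-off line.
#'
#' @param track Output of [smooth_sliding_window()].
#' @param chrom Chromosome to show (default: first).
#' @param cutoff Cut-off line (log2 units).
#' @return A ggplot.
#' @export
plot_ratio_track <- function(track, chrom = NULL, cutoff = 2) {
  chrom <- chrom %||% track$chrom[1]
  d <- filter(track, .data$chrom == !!chrom) |>
    mutate(mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid / 1e6,
                                  y = .data$smoothed_ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_grid(
      rows = if ("replicate" %in% names(d)) ggplot2::vars(.data$replicate),
      cols = if ("condition" %in% names(d)) ggplot2::vars(.data$condition)
    ) +
    ggplot2::labs(x = paste(chrom, "position (Mb)"),
                  y = "smoothed log2(e4C/control)") +
    ggplot2::theme_bw()
}

#' Plot peaks per chromosome
#'
#' @param density Output of [peak_density_by_chromosome()].
#' @return A ggplot of peaks per Mb by chromosome.
#' @export
plot_peak_density <- function(density) {
  p <- ggplot2::ggplot(density,
                       ggplot2::aes(x = .data$chrom, y = .data$peaks_per_mb)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "e4C peaks per Mb") +
    ggplot2::theme_bw()
  if ("condition" %in% names(density)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  }
  p
}

#' Plot FISH association frequencies
#'
#' @param freq `frequencies` tibble from [association_frequencies()].
#' @return A ggplot with binomial standard-error bars.
#' @export
plot_association_frequencies <- function(freq) {
  d <- mutate(freq,
              se = sqrt(.data$fraction * (1 - .data$fraction) /
                          .data$n_total))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fraction - .data$se,
                                        ymax = .data$fraction + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "fraction of nuclei associated (<= 500 nm)") +
    ggplot2::theme_bw()
}

#' Plot distance-bin enrichment of hits versus the array
#'
#' @param enrichment Output of [distance_enrichment()].
#' @return A ggplot of hit/array fraction ratios per bin.
#' @export
plot_distance_enrichment <- function(enrichment) {
  d <- mutate(enrichment, bin = factor(.data$bin, levels = .data$bin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$enrichment)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "distance to nearest TSS/TES",
                  y = "hit fraction / array fraction") +
    ggplot2::theme_bw()
}
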
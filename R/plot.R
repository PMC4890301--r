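#' Plot chromosome paints as a genotype mosaic
#'
#' One horizontal bar per line, faceted by chromosome: recipient background in
#' light grey, heterozygous segments in mid grey, homozygous donor segments in
#' black — the usual graphical-genotype rendering for introgression panels.
#'
#' @param paints Paint tibble.
#' @return A ggplot object.
#' @export
plot_paints <- function(paints) {
  ils <- sort(unique(paints$il))
  df <- dplyr::mutate(paints, y = match(.data$il, ils))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start / 1e6, xmax = .data$end / 1e6,
      ymin = .data$y - 0.45, ymax = .data$y + 0.45,
      fill = .data$genotype
    )) +
    ggplot2::scale_fill_manual(values = c(HOM_P1 = "grey92", HET = "grey55",
                                          HOM_P2 = "black")) +
    ggplot2::scale_y_continuous(breaks = seq_along(ils), labels = ils) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = NULL, fill = "Genotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Plot LOD profiles from a bin-marker scan
#'
#' @param scan An `il_scan` object.
#' @param lod_threshold Dashed significance line (default 2).
#' @return A ggplot object (LOD against bin midpoint, faceted trait x
#'   chromosome, coloured by site).
#' @export
plot_scan <- function(scan, lod_threshold = 2) {
  bins <- attr(scan, "bins")
  df <- tidy(scan) |>
    dplyr::filter(!is.na(.data$lod)) |>
    dplyr::mutate(
      mid = (bins$start[match(.data$bin, bins$bin)] +
               bins$end[match(.data$bin, bins$bin)]) / 2e6
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$lod, colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = lod_threshold, linetype = "dashed") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$trait),
                        cols = ggplot2::vars(.data$chrom),
                        scales = "free") +
    ggplot2::labs(x = "Position (Mb)", y = "LOD", colour = "Site") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.il_scan <- function(object, ...) plot_scan(object, ...)

#' Histogram of bin lengths
#' @param bins Bin table from [build_bins()].
#' @return A ggplot object.
#' @export
plot_bin_lengths <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(.data$length / 1e3)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Bin length (kb)", y = "Bins") +
    ggplot2::theme_minimal()
}

#' Per-chromosome introgression coverage barplot
#' @param coverage Output of [segment_coverage()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  ggplot2::ggplot(coverage$per_chrom,
                  ggplot2::aes(.data$chrom, 100 * .data$coverage)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = 100 * coverage$genome_coverage,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Coverage of donor genome (%)") +
    ggplot2::theme_minimal()
}
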
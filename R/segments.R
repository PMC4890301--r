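#' Extract introgressed segments from paints
#'
#' Every maximal non-recipient block is one segment; because adjacent paint
#' blocks always differ in genotype, a heterozygous block adjacent to a
#' homozygous-donor block yields two segments with a shared boundary, keeping
#' the zygosity classes separately countable.
#'
#' @param paints Paint tibble (inferred or truth).
#' @return Segment tibble `il`, `chrom`, `start`, `end`, `zygosity`
#'   (`HOM_DONOR`/`HET`), `length`.
#' @export
extract_segments <- function(paints) {
  paints |>
    dplyr::filter(.data$genotype != "HOM_P1") |>
    dplyr::transmute(
      .data$il, .data$chrom, .data$start, .data$end,
      zygosity = ifelse(.data$genotype == "HET", "HET", "HOM_DONOR"),
      length = .data$end - .data$start + 1
    ) |>
    dplyr::arrange(.data$il, .data$chrom, .data$start)
}

#' Count and length statistics of introgressed segments
#'
#' @param segments Output of [extract_segments()].
#' @param n_il Panel size (lines with zero segments still count in per-line
#'   means).
#' @param genome Optional [genome_spec()]; adds the mean per-line introgressed
#'   length as a fraction of the genome.
#' @return A list: totals by zygosity, per-line count distribution, per-line
#'   mean count and length (plus a variant weighting heterozygous segments at
#'   half length), single-segment length summaries, and the fractions of
#'   segments under 5 Mb and over 10 Mb.
#' @export
segment_stats <- function(segments, n_il, genome = NULL) {
  per_il <- segments |>
    dplyr::group_by(.data$il) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      n_hom = sum(.data$zygosity == "HOM_DONOR"),
      n_het = sum(.data$zygosity == "HET"),
      total_length = sum(.data$length)
    )
  hom_len <- sum(segments$length[segments$zygosity == "HOM_DONOR"])
  het_len <- sum(segments$length[segments$zygosity == "HET"])
  out <- list(
    n_segments = nrow(segments),
    n_hom = sum(segments$zygosity == "HOM_DONOR"),
    n_het = sum(segments$zygosity == "HET"),
    per_il = per_il,
    mean_segments_per_il = nrow(segments) / n_il,
    total_length = sum(segments$length),
    mean_length_per_il = sum(segments$length) / n_il,
    mean_length_per_il_het_half = (hom_len + het_len / 2) / n_il,
    mean_segment_length = if (nrow(segments) > 0) mean(segments$length) else NA_real_,
    min_segment_length = if (nrow(segments) > 0) min(segments$length) else NA_real_,
    max_segment_length = if (nrow(segments) > 0) max(segments$length) else NA_real_,
    frac_below_5mb = if (nrow(segments) > 0) mean(segments$length < 5e6) else NA_real_,
    frac_above_10mb = if (nrow(segments) > 0) mean(segments$length > 10e6) else NA_real_
  )
  if (!is.null(genome))
    out$mean_genome_fraction_per_il <-
      out$mean_length_per_il / sum(genome$chrom$length)
  out
}

## Union of 1-based inclusive intervals; adjacent intervals are merged.
## Returns a tibble(start, end) sorted by start.
.interval_union <- function(start, end) {
  if (length(start) == 0)
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]
  end <- cummax(end[o])
  new_grp <- c(TRUE, start[-1] > end[-length(end)] + 1)
  grp <- cumsum(new_grp)
  tibble::tibble(
    start = as.numeric(tapply(start, grp, min)),
    end = as.numeric(tapply(end, grp, max))
  )
}

#' Genome coverage of the panel's introgressed segments
#'
#' Per chromosome the union across all lines of segment intervals is computed;
#' coverage is union length over chromosome length, and the complement gives
#' the uncovered gap regions.
#'
#' @param segments Output of [extract_segments()].
#' @param genome A [genome_spec()].
#' @return List with `per_chrom` (tibble `chrom`, `covered_bp`, `length`,
#'   `coverage`), `genome_coverage` (total union / total length), and `gaps`
#'   (tibble `chrom`, `start`, `end`).
#' @export
segment_coverage <- function(segments, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  res <- purrr::pmap(genome$chrom, function(chrom, length) {
    s <- segments[segments$chrom == chrom, ]
    u <- .interval_union(s$start, s$end)
    covered <- sum(u$end - u$start + 1)
    bounds <- c(0, rbind(u$start, u$end), length + 1)
    gap_start <- bounds[seq(1, length(bounds), by = 2)] + 1
    gap_end <- bounds[seq(2, length(bounds), by = 2)] - 1
    keep <- gap_start <= gap_end
    list(
      row = tibble::tibble(chrom = chrom, covered_bp = covered,
                           length = length, coverage = covered / length),
      gaps = tibble::tibble(chrom = chrom, start = gap_start[keep],
                            end = gap_end[keep])
    )
  })
  per_chrom <- dplyr::bind_rows(purrr::map(res, "row"))
  list(
    per_chrom = per_chrom,
    genome_coverage = sum(per_chrom$covered_bp) / sum(per_chrom$length),
    gaps = dplyr::bind_rows(purrr::map(res, "gaps"))
  )
}
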
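#' Overlap QTL peak intervals with annotation intervals
#'
#' The query interval of each QTL is its peak bin extended by `flank_bins`
#' adjacent bins on each side (clipped at chromosome ends); an annotation
#' colocalises when the 1-based inclusive intervals intersect.
#'
#' @param qtls QTL table with `trait`, `chrom`, `peak_bin` (and `name` if
#'   [name_qtls()] has run).
#' @param bins Bin table from [build_bins()].
#' @param annotations Tibble `id`, `chrom`, `start`, `end`, `kind` (e.g.
#'   cloned genes and selective sweeps; a sweep `signal` column, such as the
#'   wild/cultivated diversity ratio, is carried through but not filtered on).
#' @param flank_bins Bins added on each side of the peak bin (default 1).
#' @return Tibble with one row per colocalising (QTL, annotation) pair:
#'   `qtl`, `trait`, `annotation`, `kind`, `overlap_bp`, plus the query and
#'   annotation coordinates. Annotations on chromosomes absent from the bin
#'   map are an error listing the offenders.
#' @export
overlap_qtls <- function(qtls, bins, annotations, flank_bins = 1) {
  stopifnot(flank_bins >= 0)
  unknown <- setdiff(unique(annotations$chrom), unique(bins$chrom))
  if (length(unknown) > 0)
    stop("annotations on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  qtl_label <- if ("name" %in% names(qtls)) qtls$name
  else paste0(qtls$trait, "@bin", qtls$peak_bin)
  purrr::map_dfr(seq_len(nrow(qtls)), function(i) {
    b <- bins[bins$chrom == qtls$chrom[i], ]
    lo <- max(min(b$bin), qtls$peak_bin[i] - flank_bins)
    hi <- min(max(b$bin), qtls$peak_bin[i] + flank_bins)
    q_start <- b$start[b$bin == lo]
    q_end <- b$end[b$bin == hi]
    a <- annotations[annotations$chrom == qtls$chrom[i] &
                       annotations$start <= q_end &
                       annotations$end >= q_start, ]
    if (nrow(a) == 0) return(NULL)
    tibble::tibble(
      qtl = qtl_label[i], trait = qtls$trait[i], chrom = qtls$chrom[i],
      annotation = a$id, kind = a$kind,
      overlap_bp = pmin(q_end, a$end) - pmax(q_start, a$start) + 1,
      q_start = q_start, q_end = q_end, a_start = a$start, a_end = a$end
    )
  })
}

#' Group QTLs of different traits sharing a peak bin into clusters
#'
#' @param qtls QTL table with `trait` and `peak_bin` (and optionally `name`,
#'   `chrom`).
#' @return Tibble `cluster`, `peak_bin`, `chrom`, `n_traits`, `traits`
#'   (comma-joined, sorted), `members` (names or trait labels, sorted); one
#'   row per bin shared by two or more traits. Membership does not depend on
#'   input order.
#' @export
qtl_clusters <- function(qtls) {
  label <- if ("name" %in% names(qtls)) qtls$name else qtls$trait
  df <- tibble::tibble(peak_bin = qtls$peak_bin, trait = qtls$trait,
                       chrom = if ("chrom" %in% names(qtls)) qtls$chrom else NA,
                       label = label)
  df |>
    dplyr::group_by(.data$peak_bin) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      n_traits = dplyr::n_distinct(.data$trait),
      traits = paste(sort(unique(.data$trait)), collapse = ","),
      members = paste(sort(unique(.data$label)), collapse = ",")
    ) |>
    dplyr::filter(.data$n_traits >= 2) |>
    dplyr::arrange(.data$peak_bin) |>
    dplyr::mutate(cluster = dplyr::row_number(), .before = 1)
}
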
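#' Tidy a bin-marker scan
#' @param x An `il_scan` object from [scan_qtl()].
#' @param ... Unused.
#' @return A plain tibble of scan points.
#' @export
tidy.il_scan <- function(x, ...) {
  out <- x
  attr(out, "bins") <- NULL
  class(out) <- setdiff(class(out), "il_scan")
  tibble::as_tibble(out)
}

#' One-row summary of a bin-marker scan
#' @param x An `il_scan` object.
#' @param lod_threshold Threshold used for the significant-point count.
#' @param ... Unused.
#' @export
glance.il_scan <- function(x, lod_threshold = 2, ...) {
  tibble::tibble(
    n_traits = dplyr::n_distinct(x$trait),
    n_sites = dplyr::n_distinct(x$site),
    n_bins = dplyr::n_distinct(x$bin),
    n_points = sum(!is.na(x$lod)),
    max_lod = max(x$lod[is.finite(x$lod)], na.rm = TRUE),
    n_significant = sum(x$lod >= lod_threshold, na.rm = TRUE)
  )
}

#' Tidy a QTL table into one row per (QTL, site)
#' @param x An `il_qtl` object from [call_qtls()].
#' @param ... Unused.
#' @export
tidy.il_qtl <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble::tibble(trait = character(), chrom = character(),
                          name = character(), site = character(),
                          peak_bin = integer(), lod = numeric(),
                          r2 = numeric(), additive = numeric(), n = integer()))
  }
  base <- tibble::as_tibble(x)
  purrr::map_dfr(seq_len(nrow(base)), function(i) {
    ss <- base$site_stats[[i]]
    tibble::tibble(
      trait = base$trait[i], chrom = base$chrom[i],
      name = if ("name" %in% names(base)) base$name[i] else NA_character_,
      site = ss$site, peak_bin = ss$peak_bin, lod = ss$lod, r2 = ss$r2,
      additive = ss$additive, n = ss$n
    )
  })
}

#' One-row summary of a QTL table
#' @param x An `il_qtl` object.
#' @param ... Unused.
#' @export
glance.il_qtl <- function(x, ...) {
  tibble::tibble(
    n_qtls = nrow(x),
    n_traits = dplyr::n_distinct(x$trait),
    n_both_sites = sum(x$both_sites),
    n_donor_positive = sum(purrr::map_dbl(x$site_stats, function(s) {
      s$additive[which.max(s$lod)]
    }) > 0)
  )
}
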
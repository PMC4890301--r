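#' Filter candidate parental SNP sites
#'
#' Applies the site-quality rules in a fixed order and reports removals per
#' rule: base quality strictly above `min_base_quality`, parental mapping
#' quality strictly above `min_parent_mapq`, both parental alleles supported
#' by at least `min_allele_reads` reads, biallelic only, and a greedy
#' left-to-right spacing rule that keeps a site only if it is at least
#' `min_spacing_bp` from the previously retained site on the chromosome
#' (the earlier of a close pair wins).
#'
#' @param sites Site tibble as produced by [simulate_parents()], sorted by
#'   (chrom, pos); unsorted input is an error, not silently reordered.
#' @param min_base_quality Base quality must exceed this (default 25).
#' @param min_parent_mapq Parental mapping quality must exceed this (default 40).
#' @param min_allele_reads Minimum reads supporting each parental allele
#'   (default 4, inclusive).
#' @param min_spacing_bp Minimum distance between retained sites (default 10,
#'   inclusive).
#' @return The retained sites, with the per-rule removal counts attached as a
#'   tibble in `attr(, "filter_report")` (see [filter_report()]).
#' @export
filter_sites <- function(sites, min_base_quality = 25, min_parent_mapq = 40,
                         min_allele_reads = 4, min_spacing_bp = 10) {
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) > 0) {
    runs <- rle(sites$chrom)$values
    if (anyDuplicated(runs) > 0)
      stop("sites are not grouped by chromosome; sort by (chrom, pos) first")
    bad <- sites |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(unsorted = is.unsorted(.data$pos, strictly = TRUE))
    if (any(bad$unsorted))
      stop("site positions are not strictly increasing on: ",
           paste(bad$chrom[bad$unsorted], collapse = ", "))
  }
  report <- tibble::tibble(rule = character(), removed = integer(),
                           kept_after = integer())
  apply_rule <- function(df, rule, keep) {
    report <<- dplyr::bind_rows(report, tibble::tibble(
      rule = rule, removed = sum(!keep), kept_after = sum(keep)))
    df[keep, , drop = FALSE]
  }
  out <- sites
  out <- apply_rule(out, "base_quality", out$base_qual > min_base_quality)
  out <- apply_rule(out, "parent_mapq", out$parent_mapq > min_parent_mapq)
  out <- apply_rule(out, "allele_reads",
                    out$depth_p1 >= min_allele_reads &
                      out$depth_p2 >= min_allele_reads)
  out <- apply_rule(out, "biallelic", out$biallelic)
  keep_spacing <- function(pos) {
    keep <- logical(length(pos))
    last <- -Inf
    for (i in seq_along(pos)) {
      if (pos[i] - last >= min_spacing_bp) {
        keep[i] <- TRUE
        last <- pos[i]
      }
    }
    keep
  }
  keep <- if (nrow(out) == 0) logical(0) else
    as.logical(unlist(lapply(split(out$pos, factor(out$chrom, unique(out$chrom))),
                             keep_spacing), use.names = FALSE))
  out <- apply_rule(out, "spacing", keep)
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the per-rule removal report from a filtered site table
#' @param sites Output of [filter_sites()].
#' @return Tibble with columns `rule`, `removed`, `kept_after`.
#' @export
filter_report <- function(sites) {
  rep <- attr(sites, "filter_report")
  if (is.null(rep)) stop("no filter report attached; was this filtered with filter_sites()?")
  rep
}

#' Mask low-mapping-quality IL observations
#'
#' Observations whose line-side mapping quality does not exceed `min_il_mapq`
#' are set to missing (both read counts zeroed) but remain in the table, so
#' downstream site indexing is unchanged.
#'
#' @param obs Observation tibble with columns `reads_p1`, `reads_p2`, `mapq`.
#' @param min_il_mapq IL mapping quality must exceed this (default 20).
#' @return The observation tibble with sub-threshold rows masked.
#' @export
filter_observations <- function(obs, min_il_mapq = 20) {
  obs <- tibble::as_tibble(obs)
  if (!"mapq" %in% names(obs)) stop("observations lack a 'mapq' column")
  masked <- obs$mapq <= min_il_mapq
  obs$reads_p1[masked] <- 0L
  obs$reads_p2[masked] <- 0L
  obs
}
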
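## Readers and writers for the pipeline's on-disk dialects. Tables are plain
## TSV via readr; variants additionally round-trip through VCF (one sample per
## line, allele depths in AD); interval annotations come in as BED (0-based
## half-open, converted on read) or GFF3.

#' @rdname il_io
#' @param x Table to write.
#' @param path File path.
#' @export
write_sites_tsv <- function(x, path) readr::write_tsv(x, path)

#' @rdname il_io
#' @export
read_sites_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c"))
}

#' @rdname il_io
#' @export
write_observations_tsv <- function(x, path) readr::write_tsv(x, path)

#' @rdname il_io
#' @export
read_observations_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(il = "c", chrom = "c"))
}

#' @rdname il_io
#' @export
write_paints_tsv <- function(x, path) readr::write_tsv(x, path)

#' @rdname il_io
#' @export
read_paints_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(il = "c", chrom = "c"))
}

#' @rdname il_io
#' @export
write_phenotypes_tsv <- function(x, path) readr::write_tsv(x, path)

#' @rdname il_io
#' @export
read_phenotypes_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(il = "c", site = "c", trait = "c"))
}

#' Tabular input/output for pipeline stages
#'
#' Thin TSV readers/writers with stable column types for the site,
#' observation, paint, phenotype, bin, and bin-genotype tables.
#'
#' @name il_io
#' @rdname il_io
#' @export
write_bins_tsv <- function(x, path) readr::write_tsv(x, path)

#' @rdname il_io
#' @export
read_bins_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", bin = "i"))
}

#' @rdname il_io
#' @export
write_bin_genotypes_tsv <- function(x, path) readr::write_tsv(x, path)

#' @rdname il_io
#' @export
read_bin_genotypes_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(il = "c", bin = "i", code = "i"))
}

#' Write sites and per-line allele observations as a VCF
#'
#' One sample per line; the only FORMAT field is `AD` (recipient-allele,
#' donor-allele read depths). Sites without an observation for a line are
#' written as missing (`.`).
#'
#' @param sites Site table (needs `chrom`, `pos`, `allele_p1`, `allele_p2`;
#'   `base_qual` becomes QUAL when present).
#' @param obs Observation table (`il`, `chrom`, `pos`, `reads_p1`, `reads_p2`).
#' @param path Output path (plain text).
#' @param genome Optional [genome_spec()] for contig header lines.
#' @export
write_vcf <- function(sites, obs, path, genome = NULL) {
  ils <- sort(unique(obs$il))
  key <- paste(sites$chrom, sites$pos)
  ad <- matrix(".", nrow = nrow(sites), ncol = length(ils),
               dimnames = list(NULL, ils))
  idx <- match(paste(obs$chrom, obs$pos), key)
  keep <- !is.na(idx)
  ad[cbind(idx[keep], match(obs$il[keep], ils))] <-
    paste0(obs$reads_p1[keep], ",", obs$reads_p2[keep])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ilbinmap",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", genome$chrom$chrom,
              as.integer(genome$chrom$length)),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (P1,P2)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ils), collapse = "\t")
  )
  qual <- if ("base_qual" %in% names(sites)) sites$base_qual else "."
  body <- paste(sites$chrom, as.integer(sites$pos), ".", sites$allele_p1,
                sites$allele_p2, qual, ".", ".", "AD",
                apply(ad, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()] (or any VCF carrying AD)
#'
#' @param path VCF path.
#' @return List with `sites` (`chrom`, `pos`, `allele_p1`, `allele_p2`,
#'   `base_qual`) and `observations` (`il`, `chrom`, `pos`, `reads_p1`,
#'   `reads_p2`); samples with missing AD at a site get zero depths.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    allele_p1 = fix[, "REF"], allele_p2 = fix[, "ALT"],
    base_qual = suppressWarnings(as.numeric(fix[, "QUAL"]))
  )
  ad <- vcfR::extract.gt(v, element = "AD")
  obs <- tibble::as_tibble(ad, rownames = NULL) |>
    dplyr::mutate(chrom = sites$chrom, pos = sites$pos) |>
    tidyr::pivot_longer(cols = -c("chrom", "pos"), names_to = "il",
                        values_to = "ad") |>
    tidyr::separate_wider_delim("ad", ",", names = c("reads_p1", "reads_p2"),
                                too_few = "align_start") |>
    dplyr::mutate(
      reads_p1 = dplyr::coalesce(suppressWarnings(as.integer(.data$reads_p1)), 0L),
      reads_p2 = dplyr::coalesce(suppressWarnings(as.integer(.data$reads_p2)), 0L)
    ) |>
    dplyr::select("il", "chrom", "pos", "reads_p1", "reads_p2") |>
    dplyr::arrange(.data$il, .data$chrom, .data$pos)
  list(sites = sites, observations = obs)
}

#' Read interval annotations from BED or GFF3
#'
#' BED's 0-based half-open coordinates are converted to the package's 1-based
#' inclusive convention on read (rtracklayer does the conversion; it is
#' unit-tested in both directions).
#'
#' @param path File path (`.bed`, `.gff`, `.gff3`).
#' @param kind Value for the `kind` column (e.g. `"gene"` or `"sweep"`).
#' @return Tibble `id`, `chrom`, `start`, `end`, `kind` (plus `signal` when a
#'   BED score is present).
#' @export
read_annotations <- function(path, kind = "gene") {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  id <- if (!is.null(df$name)) as.character(df$name)
  else if (!is.null(df$ID)) as.character(df$ID)
  else sprintf("%s%05d", kind, seq_len(nrow(df)))
  out <- tibble::tibble(id = id, chrom = as.character(df$seqnames),
                        start = df$start, end = df$end, kind = kind)
  if (!is.null(df$score) && !all(is.na(df$score))) out$signal <- df$score
  out
}

#' Read gene features from a GFF3 annotation
#'
#' @param path GFF3 path.
#' @return Tibble `id`, `chrom`, `start`, `end`, `kind = "gene"` (1-based
#'   inclusive, as GFF already is).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!is.null(df$type)) df <- df[df$type == "gene", , drop = FALSE]
  id <- if (!is.null(df$ID) && !all(is.na(df$ID))) as.character(df$ID)
  else if (!is.null(df$Name)) as.character(df$Name)
  else sprintf("gene%05d", seq_len(nrow(df)))
  tibble::tibble(id = id, chrom = as.character(df$seqnames),
                 start = df$start, end = df$end, kind = "gene")
}

#' Write 1-based inclusive intervals as BED
#'
#' Converts to BED's 0-based half-open convention on write via rtracklayer.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally `id`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end)
  )
  if ("id" %in% names(intervals)) names(gr) <- intervals$id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
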
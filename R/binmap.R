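## Validate that a paint tibble partitions every chromosome of the genome.
.check_partition <- function(paints, genome) {
  lens <- stats::setNames(genome$chrom$length, genome$chrom$chrom)
  bad <- paints |>
    dplyr::group_by(.data$il, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(ok = dplyr::first(.data$start) == 1 &&
                       dplyr::last(.data$end) == lens[[dplyr::first(.data$chrom)]] &&
                       all(.data$start[-1] == .data$end[-dplyr::n()] + 1),
                     .groups = "drop")
  if (!all(bad$ok)) {
    off <- bad[!bad$ok, ]
    stop("paints do not partition the chromosome for: ",
         paste(paste0(off$il, "/", off$chrom), collapse = ", "))
  }
  invisible(TRUE)
}

#' Build the population-wide skeleton bin map
#'
#' Per chromosome, the sorted union of all lines' breakpoint positions
#' partitions `[1, L]` into candidate bins; adjacent candidate bins whose
#' genotype columns are identical across every line are merged, so the final
#' map is maximal (no two adjacent bins agree in all lines). Within a bin no
#' line recombines, so the bin acts as a single marker.
#'
#' @param paints Paint tibble for the whole panel.
#' @param genome A [genome_spec()].
#' @return Bin tibble `bin` (ordinal, genome-ordered), `chrom`, `start`,
#'   `end`, `length`; bins tile each chromosome exactly.
#' @export
build_bins <- function(paints, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  .check_partition(paints, genome)
  ils <- sort(unique(paints$il))
  paint_split <- split(paints, paste(paints$il, paints$chrom, sep = "\r"))
  per_chrom <- purrr::pmap(genome$chrom, function(chrom, length) {
    cuts <- paints[paints$chrom == chrom & paints$end < length, ][["end"]]
    cuts <- sort(unique(cuts))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, length)
    ## n_il x n_candidate genotype-code matrix; each candidate bin is
    ## genotypically constant within every line by construction
    M <- vapply(ils, function(id) {
      blk <- paint_split[[paste(id, chrom, sep = "\r")]]
      if (is.null(blk)) stop("no paint for ", id, " on ", chrom)
      .code_at(blk$end, geno_code(blk$genotype), starts)
    }, integer(length(starts)))
    M <- matrix(M, nrow = length(starts))
    if (length(starts) > 1) {
      differs <- rowSums(M[-1, , drop = FALSE] !=
                           M[-nrow(M), , drop = FALSE]) > 0
      grp <- cumsum(c(TRUE, differs))
    } else {
      grp <- 1L
    }
    tibble::tibble(
      chrom = chrom,
      start = as.numeric(tapply(starts, grp, min)),
      end = as.numeric(tapply(ends, grp, max))
    )
  })
  dplyr::bind_rows(per_chrom) |>
    dplyr::mutate(bin = dplyr::row_number(),
                  length = .data$end - .data$start + 1) |>
    dplyr::select("bin", "chrom", "start", "end", "length")
}

#' Line-by-bin genotype matrix in long form
#'
#' @param bins Bin table from [build_bins()].
#' @param paints The paint tibble the bins were built from.
#' @return Tibble `il`, `bin`, `genotype`, `code` (0 = HOM_P1, 1 = HET,
#'   2 = HOM_P2), one row per (line, bin). A line whose paint changes
#'   genotype inside a bin is a hard error: it indicates the bins were not
#'   built from these paints.
#' @export
bin_genotypes <- function(bins, paints) {
  ils <- sort(unique(paints$il))
  paint_split <- split(paints, paste(paints$il, paints$chrom, sep = "\r"))
  bins_split <- split(bins[c("bin", "chrom", "start", "end")], bins$chrom)
  M <- matrix(NA_integer_, nrow = length(ils), ncol = nrow(bins))
  for (i in seq_along(ils)) {
    for (b in bins_split) {
      blk <- paint_split[[paste(ils[i], b$chrom[1], sep = "\r")]]
      if (is.null(blk)) stop("no paint for ", ils[i], " on ", b$chrom[1])
      cuts <- blk$end[-nrow(blk)]
      if (!all(cuts %in% b$end))
        stop("paint of ", ils[i], " changes genotype inside a bin on ",
             b$chrom[1], "; bins are inconsistent with these paints")
      M[i, b$bin] <- .code_at(blk$end, geno_code(blk$genotype), b$start)
    }
  }
  code <- as.integer(t(M))
  tibble::tibble(
    il = rep(ils, each = nrow(bins)),
    bin = rep(bins$bin, length(ils)),
    genotype = geno_label(code),
    code = code
  )
}

#' Widen a long bin-genotype table into a lines x bins matrix
#' @param bin_geno Output of [bin_genotypes()].
#' @return Integer matrix (rows = lines, columns = bins, codes 0/1/2).
#' @export
bin_matrix <- function(bin_geno) {
  wide <- tidyr::pivot_wider(bin_geno[c("il", "bin", "code")],
                             names_from = "bin", values_from = "code")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$il
  storage.mode(m) <- "integer"
  m
}

#' Summary statistics of a bin map
#'
#' Reports bin-length summaries overall and per chromosome, and, when a gene
#' annotation is supplied, genes per bin and the fraction of bins with fewer
#' than 10 genes. A gene is assigned to the bin containing its interval
#' midpoint (`gene_mode = "midpoint"`, additive across bins) or to every bin
#' it overlaps (`"overlap"`). Optional centromere intervals only label bins
#' for a centromeric-vs-arm length comparison.
#'
#' @param bins Bin table from [build_bins()].
#' @param genes Optional tibble `chrom`, `start`, `end` (e.g. from
#'   [read_gff_genes()]).
#' @param centromeres Optional tibble `chrom`, `start`, `end`.
#' @param gene_mode Gene-to-bin assignment rule.
#' @return A list: `n_bins`, `mean_length`, `min_length`, `max_length`,
#'   `length_histogram`, `per_chrom`, and with genes also `genes_per_bin`,
#'   `mean_genes`, `n_below_10_genes`, `pct_below_10_genes`; with centromeres
#'   also `centromere_comparison`.
#' @export
bin_stats <- function(bins, genes = NULL, centromeres = NULL,
                      gene_mode = c("midpoint", "overlap")) {
  gene_mode <- match.arg(gene_mode)
  out <- list(
    n_bins = nrow(bins),
    mean_length = mean(bins$length),
    min_length = min(bins$length),
    max_length = max(bins$length),
    length_histogram = bins |>
      dplyr::count(len_class = cut(.data$length / 1e3,
                                   breaks = c(0, 10, 50, 100, 250, 500, 1000, Inf),
                                   labels = c("<10kb", "10-50kb", "50-100kb",
                                              "100-250kb", "250-500kb",
                                              "0.5-1Mb", ">1Mb"))),
    per_chrom = bins |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(n_bins = dplyr::n(),
                       mean_length = mean(.data$length),
                       total_length = sum(.data$length))
  )
  if (!is.null(genes)) {
    counts <- integer(nrow(bins))
    for (ch in unique(bins$chrom)) {
      b <- bins[bins$chrom == ch, ]
      g <- genes[genes$chrom == ch, ]
      if (nrow(g) == 0) next
      if (gene_mode == "midpoint") {
        mid <- floor((g$start + g$end) / 2)
        mid <- mid[mid >= min(b$start) & mid <= max(b$end)]
        idx <- findInterval(mid - 0.5, b$end) + 1L  # start boundaries inclusive
        tab <- table(idx)
        counts[b$bin[as.integer(names(tab))]] <-
          counts[b$bin[as.integer(names(tab))]] + as.integer(tab)
      } else {
        for (i in seq_len(nrow(b))) {
          counts[b$bin[i]] <- counts[b$bin[i]] +
            sum(g$start <= b$end[i] & g$end >= b$start[i])
        }
      }
    }
    out$genes_per_bin <- tibble::tibble(bin = bins$bin, n_genes = counts)
    out$mean_genes <- mean(counts)
    out$n_below_10_genes <- sum(counts < 10)
    out$pct_below_10_genes <- 100 * sum(counts < 10) / nrow(bins)
  }
  if (!is.null(centromeres)) {
    cen <- rep(FALSE, nrow(bins))
    for (i in seq_len(nrow(centromeres))) {
      hit <- bins$chrom == centromeres$chrom[i] &
        bins$start <= centromeres$end[i] & bins$end >= centromeres$start[i]
      cen <- cen | hit
    }
    out$centromere_comparison <- tibble::tibble(
      region = c("centromeric", "arm"),
      n_bins = c(sum(cen), sum(!cen)),
      mean_length = c(mean(bins$length[cen]), mean(bins$length[!cen]))
    )
  }
  out
}
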
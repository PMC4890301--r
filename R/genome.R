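#' Genome specification for the simulator
#'
#' Describes the simulated genome: chromosome count and lengths, a uniform
#' recombination rate, and the diagnostic-SNP density between the two parents.
#' The defaults are a desk-scale genome of 12 chromosomes of 25 Mb; passing
#' `scale = "full"` swaps in rice-like chromosome lengths totalling 373 Mb.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length(s) in bp, recycled to `n_chrom`.
#' @param recomb_rate Recombination rate in cM/Mb, uniform along chromosomes.
#' @param snp_density Expected diagnostic SNPs per bp between the parents
#'   (default 4.9 per 10 kb).
#' @param min_spacing Minimum distance in bp between adjacent SNPs.
#' @param scale `"desk"` (default) keeps `chrom_length` as given; `"full"`
#'   replaces the lengths with 12 rice-like chromosomes summing to 373 Mb.
#' @return An object of class `genome_spec`: a list with a `chrom` tibble
#'   (`chrom`, `length`) plus the rate/density/spacing parameters.
#' @export
#' @examples
#' genome_spec()
#' genome_spec(n_chrom = 2, chrom_length = 1e6)
genome_spec <- function(n_chrom = 12, chrom_length = 25e6, recomb_rate = 4,
                        snp_density = 4.9e-4, min_spacing = 10,
                        scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    chrom_length <- c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2,
                      29.7, 28.4, 23.0, 23.2, 29.0, 27.5) * 1e6
    n_chrom <- 12
  }
  stopifnot(n_chrom >= 1, length(chrom_length) >= 1)
  chrom_length <- rep_len(chrom_length, n_chrom)
  if (any(chrom_length <= 0)) stop("chromosome lengths must be > 0")
  if (recomb_rate < 0) stop("recombination rate must be >= 0")
  if (snp_density < 0) stop("SNP density must be >= 0")
  if (min_spacing < 1) stop("minimum SNP spacing must be >= 1 bp")
  structure(
    list(
      chrom = tibble::tibble(
        chrom  = sprintf("chr%02d", seq_len(n_chrom)),
        length = as.numeric(floor(chrom_length))
      ),
      recomb_rate = recomb_rate,
      snp_density = snp_density,
      min_spacing = min_spacing
    ),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosomes, %.1f Mb total\n",
              nrow(x$chrom), sum(x$chrom$length) / 1e6))
  cat(sprintf("  recombination %.2f cM/Mb; SNP density %.3g/bp (>= %d bp apart)\n",
              x$recomb_rate, x$snp_density, x$min_spacing))
  invisible(x)
}

#' Breeding scheme for the simulated panel
#'
#' The panel emulates BC3F7-style introgression lines: each line descends from
#' an F1 through `n_backcross` backcrosses to the recipient parent followed by
#' `n_selfing` generations of single-seed-descent selfing.
#'
#' @param n_backcross Backcross generations to the recipient (default 3).
#' @param n_selfing Selfing generations (default 6).
#' @param n_il Number of independent lines in the panel (default 131).
#' @param interference Crossover model: `"none"` draws Poisson crossover counts
#'   per chromosome; `"obligate"` adds one guaranteed crossover per meiosis.
#' @return An object of class `breeding_scheme`.
#' @export
breeding_scheme <- function(n_backcross = 3, n_selfing = 6, n_il = 131,
                            interference = c("none", "obligate")) {
  interference <- match.arg(interference)
  stopifnot(n_backcross >= 0, n_selfing >= 0, n_il >= 1)
  structure(
    list(n_backcross = as.integer(n_backcross),
         n_selfing = as.integer(n_selfing),
         n_il = as.integer(n_il),
         interference = interference),
    class = "breeding_scheme"
  )
}

#' @export
print.breeding_scheme <- function(x, ...) {
  cat(sprintf("<breeding_scheme> %d ILs: BC%dF%d (%s interference)\n",
              x$n_il, x$n_backcross, x$n_selfing + 1L, x$interference))
  invisible(x)
}

#' Read-sampling model for low-coverage resequencing
#'
#' @param mean_depth Mean read depth per SNP (Poisson lambda, default 2.83).
#' @param error_rate Per-read probability of reporting the wrong allele
#'   (symmetric flip, default 0.01).
#' @return An object of class `read_model`.
#' @export
read_model <- function(mean_depth = 2.83, error_rate = 0.01) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(mean_depth = mean_depth, error_rate = error_rate),
            class = "read_model")
}

#' Additive trait model for simulated phenotypes
#'
#' A trait's value in line i at a site (environment) is
#' `mean + sum_j effect_j * x_ij + N(0, sd^2)`, where `x` codes the line's
#' genotype over the causal interval as -1 (recipient homozygote), 0
#' (heterozygote), +1 (donor homozygote). A positive effect therefore means
#' the donor allele increases the trait.
#'
#' @param traits Tibble with columns `trait`, `site`, `mean`, `sd` (one row per
#'   trait x environment; `sd` > 0).
#' @param qtls Tibble with columns `trait`, `chrom`, `start`, `end`, `effect`
#'   giving the causal intervals, or NULL for a purely environmental model.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(traits, qtls = NULL) {
  traits <- tibble::as_tibble(traits)
  stopifnot(all(c("trait", "site", "mean", "sd") %in% names(traits)))
  if (any(traits$sd <= 0)) stop("residual sd must be > 0 for every trait/site")
  if (anyDuplicated(traits[c("trait", "site")]))
    stop("one row per (trait, site) required")
  if (!is.null(qtls)) {
    qtls <- tibble::as_tibble(qtls)
    stopifnot(all(c("trait", "chrom", "start", "end", "effect") %in% names(qtls)))
    if (any(qtls$start > qtls$end) || any(qtls$start < 1))
      stop("causal intervals must satisfy 1 <= start <= end")
    if (!all(qtls$trait %in% traits$trait))
      stop("qtls reference traits absent from the trait table")
  }
  structure(list(traits = traits, qtls = qtls), class = "trait_model")
}
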
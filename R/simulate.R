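## Forward-in-time simulator of an introgression-line panel.
##
## A haplotype is a run-length mosaic of parental origins along one
## chromosome: list(ends = integer bp of segment right ends (last = L),
## orig = 1L for recipient, 2L for donor). Gametes are formed with a
## crossover count per chromosome ~ Poisson(length_cM / 100) and uniform
## crossover positions (no interference by default).

.new_hap <- function(L, origin) list(ends = L, orig = origin)

## Piece of haplotype h covering (a, b], as ends/orig vectors.
.hap_slice <- function(h, a, b) {
  starts <- c(0, h$ends[-length(h$ends)])
  idx <- which(h$ends > a & starts < b)
  list(ends = pmin(h$ends[idx], b), orig = h$orig[idx])
}

## One gamete from the diplotype (h1, h2) on a chromosome of L bp / cM cM.
.gamete_chr <- function(h1, h2, L, cM, interference = "none") {
  n_co <- rpois(1L, cM / 100)
  if (interference == "obligate") n_co <- n_co + 1L
  cuts <- if (n_co > 0) sort(unique(floor(runif(n_co, 1, L)))) else numeric(0)
  bounds <- unique(c(cuts, L))
  cur <- sample.int(2L, 1L)
  ends <- numeric(0)
  orig <- integer(0)
  a <- 0
  for (b in bounds) {
    s <- .hap_slice(if (cur == 1L) h1 else h2, a, b)
    ends <- c(ends, s$ends)
    orig <- c(orig, s$orig)
    a <- b
    cur <- 3L - cur
  }
  keep <- c(orig[-1L] != orig[-length(orig)], TRUE)
  list(ends = ends[keep], orig = orig[keep])
}

## Genotype mosaic of a diplotype: ends + codes 0/1/2.
.diplo_paint <- function(h1, h2) {
  ends <- sort(unique(c(h1$ends, h2$ends)))
  i1 <- findInterval(ends - 0.5, h1$ends) + 1L
  i2 <- findInterval(ends - 0.5, h2$ends) + 1L
  code <- (h1$orig[i1] - 1L) + (h2$orig[i2] - 1L)
  keep <- c(code[-1L] != code[-length(code)], TRUE)
  list(ends = ends[keep], code = code[keep])
}

## Genotype code of a paint (block ends/codes) at positions pos.
.code_at <- function(ends, code, pos) code[findInterval(pos - 0.5, ends) + 1L]

#' Simulate the diagnostic SNP set between the two parents
#'
#' Positions are drawn per chromosome as a renewal process with integer gaps
#' `min_spacing + Poisson(1/density - min_spacing)`, which realises the
#' expected density exactly while enforcing the minimum spacing. Each site is
#' biallelic with distinct parental alleles and carries the upstream quality
#' metadata the site filter consumes (base quality, parental mapping quality,
#' per-parent supporting depth, biallelic flag).
#'
#' @param spec A [genome_spec()].
#' @param seed Optional integer seed; fixed seeds give bit-identical output.
#' @return Tibble with one row per SNP: `chrom`, `pos`, `allele_p1`,
#'   `allele_p2`, `base_qual`, `parent_mapq`, `biallelic`, `depth_p1`,
#'   `depth_p2`, sorted by (chrom, pos).
#' @export
simulate_parents <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  if (spec$snp_density == 0) {
    return(tibble::tibble(
      chrom = character(), pos = numeric(),
      allele_p1 = character(), allele_p2 = character(),
      base_qual = numeric(), parent_mapq = numeric(), biallelic = logical(),
      depth_p1 = integer(), depth_p2 = integer()
    ))
  }
  mean_gap <- 1 / spec$snp_density
  if (mean_gap <= spec$min_spacing) {
    stop("SNP density incompatible with minimum spacing: expected gap ",
         round(mean_gap, 2), " bp <= min_spacing ", spec$min_spacing, " bp")
  }
  with_seed_(seed, {
    sites <- purrr::pmap_dfr(spec$chrom, function(chrom, length) {
      pos <- numeric(0)
      last <- 0
      repeat {
        need <- max(16L, ceiling((length - last) / mean_gap * 1.25) + 16L)
        gaps <- spec$min_spacing + rpois(need, mean_gap - spec$min_spacing)
        pos <- c(pos, last + cumsum(gaps))
        last <- pos[length(pos)]
        if (last > length) break
      }
      tibble::tibble(chrom = chrom, pos = pos[pos <= length])
    })
    n <- nrow(sites)
    nuc <- c("A", "C", "G", "T")
    a1 <- sample.int(4L, n, replace = TRUE)
    a2 <- 1L + (a1 - 1L + sample.int(3L, n, replace = TRUE)) %% 4L
    sites$allele_p1 <- nuc[a1]
    sites$allele_p2 <- nuc[a2]
    ## upstream-QC metadata, emulating ~13.6x parental resequencing
    sites$base_qual <- pmax(2, round(rnorm(n, 36, 5)))
    sites$parent_mapq <- sample(c(60, 30), n, replace = TRUE, prob = c(0.98, 0.02))
    sites$biallelic <- runif(n) > 0.005
    sites$depth_p1 <- rpois(n, 13.6)
    sites$depth_p2 <- rpois(n, 13.6)
    sites
  })
}

#' Simulate the introgression-line panel (ground-truth genotype mosaics)
#'
#' Each line starts from a genome-wide heterozygous F1, is backcrossed
#' `n_backcross` times to the recipient (one gamete from the current plant,
#' one pure recipient gamete), then selfed `n_selfing` generations by
#' single-seed descent (two independent gametes from the same plant).
#'
#' @param spec A [genome_spec()].
#' @param scheme A [breeding_scheme()].
#' @param seed Optional integer seed.
#' @return A truth-paint tibble: `il`, `chrom`, `start`, `end`, `genotype`
#'   (`HOM_P1`/`HET`/`HOM_P2`); blocks partition every chromosome exactly and
#'   adjacent blocks differ in genotype.
#' @export
simulate_panel <- function(spec, scheme, seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"), inherits(scheme, "breeding_scheme"))
  lens <- spec$chrom$length
  cMs <- lens / 1e6 * spec$recomb_rate
  n_chr <- length(lens)
  ils <- sprintf("IL%03d", seq_len(scheme$n_il))
  with_seed_(seed, {
    out <- vector("list", scheme$n_il)
    for (i in seq_len(scheme$n_il)) {
      plant <- lapply(seq_len(n_chr), function(c) {
        list(h1 = .new_hap(lens[c], 1L), h2 = .new_hap(lens[c], 2L))
      })
      for (g in seq_len(scheme$n_backcross)) {
        plant <- lapply(seq_len(n_chr), function(c) {
          list(h1 = .gamete_chr(plant[[c]]$h1, plant[[c]]$h2, lens[c], cMs[c],
                                scheme$interference),
               h2 = .new_hap(lens[c], 1L))
        })
      }
      for (g in seq_len(scheme$n_selfing)) {
        plant <- lapply(seq_len(n_chr), function(c) {
          list(h1 = .gamete_chr(plant[[c]]$h1, plant[[c]]$h2, lens[c], cMs[c],
                                scheme$interference),
               h2 = .gamete_chr(plant[[c]]$h1, plant[[c]]$h2, lens[c], cMs[c],
                                scheme$interference))
        })
      }
      out[[i]] <- purrr::map_dfr(seq_len(n_chr), function(c) {
        p <- .diplo_paint(plant[[c]]$h1, plant[[c]]$h2)
        tibble::tibble(
          il = ils[i], chrom = spec$chrom$chrom[c],
          start = c(1, p$ends[-length(p$ends)] + 1), end = p$ends,
          genotype = geno_label(p$code)
        )
      })
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate low-coverage allele observations at the diagnostic SNPs
#'
#' Per line and site, read depth is Poisson(`mean_depth`); each read reports
#' the true allele with probability `1 - error_rate` at homozygous sites, and
#' either allele with probability 1/2 at heterozygous sites (symmetric flips
#' leave that 1/2 unchanged). Zero-depth sites stay in the table with both
#' read counts 0, i.e. missing.
#'
#' @param paints Truth paints from [simulate_panel()].
#' @param sites SNP table from [simulate_parents()] (or the filtered subset).
#' @param model A [read_model()].
#' @param seed Optional integer seed.
#' @return Tibble: `il`, `chrom`, `pos`, `reads_p1`, `reads_p2`, `mapq`.
#' @export
simulate_reads <- function(paints, sites, model, seed = NULL) {
  stopifnot(inherits(model, "read_model"))
  site_by_chr <- split(sites$pos, sites$chrom)
  missing_chr <- setdiff(names(site_by_chr), unique(paints$chrom))
  if (length(missing_chr) > 0)
    stop("truth paints do not cover chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  with_seed_(seed, {
    base <- paints |>
      dplyr::group_by(.data$il, .data$chrom) |>
      dplyr::group_map(function(df, key) {
        pos <- site_by_chr[[key$chrom]]
        if (is.null(pos)) return(NULL)
        code <- .code_at(df$end, geno_code(df$genotype), pos)
        tibble::tibble(il = key$il, chrom = key$chrom, pos = pos, code = code)
      }) |>
      dplyr::bind_rows()
    n <- nrow(base)
    depth <- rpois(n, model$mean_depth)
    p1_prob <- c(1 - model$error_rate, 0.5, model$error_rate)[base$code + 1L]
    base$reads_p1 <- rbinom(n, depth, p1_prob)
    base$reads_p2 <- depth - base$reads_p1
    base$mapq <- sample(c(60, 10), n, replace = TRUE, prob = c(0.995, 0.005))
    base$code <- NULL
    base
  })
}

#' Simulate phenotypes under an additive trait model
#'
#' @param paints Truth paints from [simulate_panel()].
#' @param model A [trait_model()].
#' @param seed Optional integer seed.
#' @return Tibble: `il`, `site`, `trait`, `value`.
#' @details Every causal interval must lie within a single truth block of each
#'   line; a line whose mosaic changes genotype inside a causal interval
#'   raises an error naming that line.
#' @export
simulate_phenotypes <- function(paints, model, seed = NULL) {
  stopifnot(inherits(model, "trait_model"))
  ils <- sort(unique(paints$il))
  x_at <- function(chrom, start, end) {
    vapply(ils, function(id) {
      blk <- paints[paints$il == id & paints$chrom == chrom, ]
      if (nrow(blk) == 0) stop("no paint for ", id, " on ", chrom)
      hit <- blk[blk$end >= start & blk$start <= end, ]
      g <- unique(hit$genotype)
      if (length(g) != 1) {
        stop("causal interval ", chrom, ":", start, "-", end,
             " spans a breakpoint in ", id)
      }
      geno_code(g) - 1L
    }, integer(1))
  }
  X <- NULL
  if (!is.null(model$qtls) && nrow(model$qtls) > 0) {
    X <- vapply(seq_len(nrow(model$qtls)), function(j) {
      x_at(model$qtls$chrom[j], model$qtls$start[j], model$qtls$end[j])
    }, numeric(length(ils)))
    X <- matrix(X, nrow = length(ils))
  }
  with_seed_(seed, {
    purrr::pmap_dfr(model$traits, function(trait, site, mean, sd) {
      y <- rep(mean, length(ils))
      if (!is.null(X)) {
        j <- which(model$qtls$trait == trait)
        if (length(j) > 0) y <- y + as.vector(X[, j, drop = FALSE] %*% model$qtls$effect[j])
      }
      tibble::tibble(il = ils, site = site, trait = trait,
                     value = y + rnorm(length(ils), 0, sd))
    })
  })
}

#' Simulate gene and selective-sweep annotation intervals
#'
#' Convenience generator for pipeline demonstrations: uniformly placed
#' non-overlapping "gene" intervals and a handful of wider "sweep" intervals
#' carrying a selection-signal value. Purely synthetic stand-ins for a real
#' annotation, used so the bin-stats and colocalisation stages have inputs.
#'
#' @param spec A [genome_spec()].
#' @param n_genes,n_sweeps Interval counts (genes default to ~1 per 10 kb).
#' @param gene_length,sweep_length Interval lengths in bp.
#' @param seed Optional integer seed.
#' @return Tibble: `id`, `chrom`, `start`, `end`, `kind`, `signal` (sweeps
#'   only; the conventional genome-wide significance floor for the
#'   diversity-ratio signal is 3).
#' @export
simulate_annotations <- function(spec, n_genes = NULL, n_sweeps = 20,
                                 gene_length = 3000, sweep_length = 2e5,
                                 seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  total <- sum(spec$chrom$length)
  if (is.null(n_genes)) n_genes <- round(total * 1e-4)
  with_seed_(seed, {
    place <- function(n, len, kind, prefix) {
      ch <- sample(spec$chrom$chrom, n, replace = TRUE,
                   prob = spec$chrom$length / total)
      L <- spec$chrom$length[match(ch, spec$chrom$chrom)]
      start <- floor(runif(n, 1, pmax(2, L - len)))
      tibble::tibble(id = sprintf("%s%05d", prefix, seq_len(n)),
                     chrom = ch, start = start,
                     end = pmin(L, start + len - 1), kind = kind)
    }
    genes <- place(n_genes, gene_length, "gene", "gene")
    sweeps <- place(n_sweeps, sweep_length, "sweep", "sweep")
    sweeps$signal <- round(runif(n_sweeps, 3, 15), 1)
    dplyr::bind_rows(genes, sweeps) |>
      dplyr::arrange(.data$chrom, .data$start)
  })
}
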
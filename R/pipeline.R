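#' Default pipeline configuration
#'
#' All module parameters in one nested list: the simulated genome and breeding
#' scheme, the read model, a small additive trait architecture, and the
#' filter/paint/scan/colocalise thresholds (17-SNP window, 14/5 homozygosity
#' cut-offs, k = 5 imputation, LOD 2.0, one flanking bin).
#'
#' @param scale `"desk"` (12 x 25 Mb) or `"full"` (373 Mb rice-like genome).
#' @return A nested list understood by [run_pipeline()].
#' @export
default_config <- function(scale = "desk") {
  list(
    genome = list(n_chrom = 12, chrom_length = 25e6, recomb_rate = 4,
                  snp_density = 4.9e-4, min_spacing = 10, scale = scale),
    scheme = list(n_backcross = 3, n_selfing = 6, n_il = 131,
                  interference = "none"),
    reads = list(mean_depth = 2.83, error_rate = 0.01),
    traits = list(
      table = list(
        list(trait = "YPP", site = "SiteA", mean = 50, sd = 5),
        list(trait = "YPP", site = "SiteB", mean = 45, sd = 5),
        list(trait = "SH", site = "SiteA", mean = 3, sd = 0.5),
        list(trait = "SH", site = "SiteB", mean = 3, sd = 0.5)
      ),
      qtls = list(
        list(trait = "YPP", chrom = "chr01", start = 12500000,
             end = 12500000, effect = 3),
        list(trait = "YPP", chrom = "chr05", start = 5000000,
             end = 5000000, effect = -2),
        list(trait = "SH", chrom = "chr04", start = 10000000,
             end = 10000000, effect = 2)
      )
    ),
    annotations = list(n_genes = NULL, n_sweeps = 20),
    filter = list(min_base_quality = 25, min_parent_mapq = 40,
                  min_allele_reads = 4, min_spacing_bp = 10, min_il_mapq = 20),
    paint = list(window_size = 17, hom1_min = 14, hom2_max = 5, knn = 5,
                 min_block_windows = 0),
    scan = list(lod_threshold = 2, transgressive_trait = "YPP"),
    colocalise = list(flank_bins = 1)
  )
}

#' Read a YAML pipeline configuration
#'
#' Values present in the file override the defaults; everything else keeps its
#' [default_config()] value.
#'
#' @param path YAML file path.
#' @return A config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
                        !is.null(names(over[[nm]])))
        merge_rec(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_rec(default_config(), user)
}

.config_genome <- function(cfg) {
  g <- cfg$genome
  genome_spec(n_chrom = g$n_chrom, chrom_length = g$chrom_length,
              recomb_rate = g$recomb_rate, snp_density = g$snp_density,
              min_spacing = g$min_spacing, scale = g$scale %||% "desk")
}

.config_traits <- function(cfg) {
  tt <- dplyr::bind_rows(lapply(cfg$traits$table, tibble::as_tibble))
  qq <- if (length(cfg$traits$qtls) > 0)
    dplyr::bind_rows(lapply(cfg$traits$qtls, tibble::as_tibble)) else NULL
  trait_model(tt, qq)
}

PIPELINE_STAGES <- c("simulate", "filter", "paint", "binmap", "segments",
                     "scan", "colocalise")

#' Run the pipeline end to end (or a subset of stages)
#'
#' Executes `simulate -> filter -> paint -> binmap -> segments -> scan ->
#' colocalise` into a run directory. Every stage writes TSV/JSON outputs;
#' stages not requested read their inputs from a previous run in the same
#' directory (a missing input is an error naming the stage to run first). Each
#' stage draws from its own seed derived deterministically from the master
#' seed, so a stage subset reproduces the full run's results, and a manifest
#' records the config, seed, and md5 checksum of every output.
#'
#' @param out_dir Run directory (created if needed).
#' @param config Config list (see [default_config()] / [read_config()]).
#' @param seed Master seed (small integer).
#' @param stages `"all"` or a subset of
#'   `c("simulate","filter","paint","binmap","segments","scan","colocalise")`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, config = default_config(), seed = 1,
                         stages = "all") {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  stopifnot(all(stages %in% PIPELINE_STAGES))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- .config_genome(config)
  stage_seed <- function(i) as.integer(seed) * 8L + i
  p <- function(f) file.path(out_dir, f)
  cache <- new.env(parent = emptyenv())
  need <- function(name, file, reader, producer) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    if (!file.exists(p(file)))
      stop("missing input '", file, "' for this stage; run '", producer,
           "' first", call. = FALSE)
    cache[[name]] <- reader(p(file))
    cache[[name]]
  }
  log_stage <- function(...) message("[ilbinmap] ", ...)

  if ("simulate" %in% stages) {
    log_stage("simulate: ", config$scheme$n_il, " ILs on ",
              nrow(genome$chrom), " chromosomes")
    scheme <- breeding_scheme(config$scheme$n_backcross, config$scheme$n_selfing,
                              config$scheme$n_il, config$scheme$interference)
    rm_ <- read_model(config$reads$mean_depth, config$reads$error_rate)
    sites <- simulate_parents(genome, seed = stage_seed(1L))
    truth <- simulate_panel(genome, scheme, seed = stage_seed(2L))
    obs <- simulate_reads(truth, sites, rm_, seed = stage_seed(3L))
    tm <- .config_traits(config)
    pheno <- simulate_phenotypes(truth, tm, seed = stage_seed(4L))
    ann <- simulate_annotations(genome, n_genes = config$annotations$n_genes,
                                n_sweeps = config$annotations$n_sweeps,
                                seed = stage_seed(5L))
    write_sites_tsv(sites, p("sites.tsv"))
    write_paints_tsv(truth, p("truth_paints.tsv"))
    write_observations_tsv(obs, p("observations.tsv"))
    write_vcf(sites, obs, p("observations.vcf"), genome = genome)
    write_phenotypes_tsv(pheno, p("phenotypes.tsv"))
    readr::write_tsv(ann, p("annotations.tsv"))
    write_bed(ann[ann$kind == "gene", ], p("synthetic_genes.bed"))
    cache$sites <- sites; cache$obs <- obs; cache$pheno <- pheno
    cache$annotations <- ann
  }

  if ("filter" %in% stages) {
    sites <- need("sites", "sites.tsv", read_sites_tsv, "simulate")
    obs <- need("obs", "observations.tsv", read_observations_tsv, "simulate")
    f <- config$filter
    kept <- filter_sites(sites, f$min_base_quality, f$min_parent_mapq,
                         f$min_allele_reads, f$min_spacing_bp)
    obs_f <- filter_observations(obs, f$min_il_mapq) |>
      dplyr::semi_join(kept, by = c("chrom", "pos"))
    log_stage("filter: ", nrow(kept), "/", nrow(sites), " sites retained")
    write_sites_tsv(kept, p("filtered_sites.tsv"))
    write_observations_tsv(obs_f, p("filtered_observations.tsv"))
    jsonlite::write_json(filter_report(kept), p("filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    cache$kept <- kept; cache$obs_f <- obs_f
  }

  if ("paint" %in% stages) {
    obs_f <- need("obs_f", "filtered_observations.tsv",
                  read_observations_tsv, "filter")
    pp <- config$paint
    calls <- impute_calls(call_snps(obs_f), k = pp$knn)
    paints <- paint_panel(calls, genome, window_size = pp$window_size,
                          hom1_min = pp$hom1_min, hom2_max = pp$hom2_max,
                          min_block_windows = pp$min_block_windows)
    bp <- paint_breakpoints(paints)
    co <- count_crossovers(paints)
    log_stage("paint: ", co$total, " breakpoints (",
              round(co$mean_per_il, 2), " per IL)")
    write_paints_tsv(paints, p("paints.tsv"))
    readr::write_tsv(bp, p("breakpoints.tsv"))
    jsonlite::write_json(list(total_crossovers = co$total,
                              mean_per_il = co$mean_per_il),
                         p("crossovers.json"), auto_unbox = TRUE, digits = NA)
    cache$paints <- paints
  }

  if ("binmap" %in% stages) {
    paints <- need("paints", "paints.tsv", read_paints_tsv, "paint")
    bins <- build_bins(paints, genome)
    bg <- bin_genotypes(bins, paints)
    genes <- if (!is.null(cache$annotations) || file.exists(p("annotations.tsv"))) {
      ann <- need("annotations", "annotations.tsv",
                  function(f) readr::read_tsv(f, show_col_types = FALSE),
                  "simulate")
      ann[ann$kind == "gene", ]
    } else NULL
    st <- bin_stats(bins, genes = genes)
    log_stage("binmap: ", nrow(bins), " bins, mean ",
              round(st$mean_length / 1e3), " kb")
    write_bins_tsv(bins, p("bins.tsv"))
    write_bin_genotypes_tsv(bg, p("bin_genotypes.tsv"))
    jsonlite::write_json(st[c("n_bins", "mean_length", "min_length",
                              "max_length", "mean_genes",
                              "n_below_10_genes", "pct_below_10_genes")],
                         p("bin_stats.json"), auto_unbox = TRUE, digits = NA)
    cache$bins <- bins; cache$bg <- bg
  }

  if ("segments" %in% stages) {
    paints <- need("paints", "paints.tsv", read_paints_tsv, "paint")
    segs <- extract_segments(paints)
    st <- segment_stats(segs, n_il = dplyr::n_distinct(paints$il),
                        genome = genome)
    cov <- segment_coverage(segs, genome)
    log_stage("segments: ", st$n_segments, " (", st$n_hom, " hom / ",
              st$n_het, " het), coverage ",
              round(100 * cov$genome_coverage, 2), "%")
    readr::write_tsv(segs, p("segments.tsv"))
    if (nrow(segs) > 0)
      write_bed(dplyr::mutate(segs, id = .data$il), p("segments.bed"))
    if (nrow(cov$gaps) > 0) write_bed(cov$gaps, p("gaps.bed"))
    jsonlite::write_json(
      list(n_segments = st$n_segments, n_hom = st$n_hom, n_het = st$n_het,
           mean_segments_per_il = st$mean_segments_per_il,
           mean_segment_length = st$mean_segment_length,
           total_length = st$total_length,
           genome_coverage = cov$genome_coverage,
           per_chrom_coverage = cov$per_chrom),
      p("coverage.json"), auto_unbox = TRUE, digits = NA)
    cache$segments <- segs
  }

  if ("scan" %in% stages) {
    bins <- need("bins", "bins.tsv", read_bins_tsv, "binmap")
    bg <- need("bg", "bin_genotypes.tsv", read_bin_genotypes_tsv, "binmap")
    pheno <- need("pheno", "phenotypes.tsv", read_phenotypes_tsv, "simulate")
    scan <- scan_qtl(bg, pheno, bins)
    qtls <- name_qtls(call_qtls(scan, config$scan$lod_threshold))
    log_stage("scan: ", nrow(qtls), " QTLs at LOD >= ",
              config$scan$lod_threshold)
    readr::write_tsv(tidy(scan), p("scan.tsv"))
    readr::write_tsv(tidy(qtls), p("qtls.tsv"))
    corr <- purrr::map_dfr(sort(unique(pheno$site)), function(s) {
      dplyr::mutate(correlate_traits(pheno, s), site = s, .before = 1)
    })
    readr::write_tsv(corr, p("correlations.tsv"))
    tg_trait <- config$scan$transgressive_trait
    if (tg_trait %in% pheno$trait) {
      tm <- .config_traits(config)
      eff <- sum(tm$qtls$effect[tm$qtls$trait == tg_trait] %||% 0)
      parents <- tm$traits |>
        dplyr::filter(.data$trait == tg_trait) |>
        dplyr::transmute(.data$site, value = .data$mean - eff)
      tg <- transgressive_lines(pheno, tg_trait, parents)
      readr::write_tsv(tg, p("transgressive.tsv"))
    }
    cache$qtls <- qtls
  }

  if ("colocalise" %in% stages) {
    bins <- need("bins", "bins.tsv", read_bins_tsv, "binmap")
    ann <- need("annotations", "annotations.tsv",
                function(f) readr::read_tsv(f, show_col_types = FALSE),
                "simulate")
    qtls_flat <- if (!is.null(cache$qtls)) cache$qtls else {
      if (!file.exists(p("qtls.tsv")))
        stop("missing input 'qtls.tsv' for this stage; run 'scan' first",
             call. = FALSE)
      readr::read_tsv(p("qtls.tsv"), show_col_types = FALSE) |>
        dplyr::distinct(.data$trait, .data$chrom, .data$name,
                        peak_bin = .data$peak_bin)
    }
    ov <- overlap_qtls(qtls_flat, bins, ann,
                       flank_bins = config$colocalise$flank_bins)
    cl <- qtl_clusters(qtls_flat)
    log_stage("colocalise: ", nrow(ov), " QTL-annotation overlaps, ",
              nrow(cl), " clusters")
    readr::write_tsv(ov, p("overlaps.tsv"))
    readr::write_tsv(cl, p("clusters.tsv"))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "ilbinmap",
    version = as.character(utils::packageVersion("ilbinmap")),
    seed = as.integer(seed),
    stages = stages,
    config = config,
    outputs = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(p(f))))
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
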
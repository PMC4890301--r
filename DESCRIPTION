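Package: ilbinmap
Title: Bin-Map Genotyping and QTL Scanning for Introgression-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising introgression-line (IL) panels genotyped by
    low-coverage whole-genome resequencing. Implements sliding-window genotype
    painting from per-SNP allele depths (17-SNP window, 1-SNP step, majority
    per-SNP calls with k-nearest-neighbour imputation), recombination-breakpoint
    detection, population-wide skeleton bin-map construction, introgressed-segment
    and genome-coverage statistics, bin-marker QTL scanning by single-marker
    regression (LOD, R-squared, additive effect of the donor allele), QTL naming
    and clustering, trait correlations, transgressive-line screening, and overlap
    of QTL peak intervals with gene and selective-sweep annotations. A
    forward-in-time breeding simulator (backcrossing, selfing, Poisson crossovers,
    read sampling, additive trait models) provides fully ground-truthed synthetic
    panels for validation, and a pipeline orchestrator runs all stages
    reproducibly from a single seed and config.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
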
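test_that("genome and scheme constructors validate their inputs", {
  expect_error(genome_spec(chrom_length = 0), "lengths")
  expect_error(genome_spec(recomb_rate = -1), "recombination")
  expect_error(genome_spec(min_spacing = 0), "spacing")
  expect_error(breeding_scheme(n_backcross = -1))
  expect_error(trait_model(tibble::tibble(trait = "T", site = "A",
                                          mean = 0, sd = 0)), "sd")
  full <- genome_spec(scale = "full")
  expect_equal(sum(full$chrom$length), 373e6)
})

test_that("parent SNP simulation honours density, spacing, and determinism", {
  g <- toy_genome(n_chrom = 1, len = 1e6, snp_density = 1e-4)
  s1 <- simulate_parents(g, seed = 7)
  s2 <- simulate_parents(g, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(diff(s1$pos) >= 10))
  expect_true(all(s1$allele_p1 != s1$allele_p2))
  # count within the Poisson 99% band around the expectation of 100
  expect_gte(nrow(s1), qpois(0.005, 100))
  expect_lte(nrow(s1), qpois(0.995, 100))
  # zero density -> empty table; incompatible density -> rejected
  expect_equal(nrow(simulate_parents(toy_genome(snp_density = 0))), 0)
  expect_error(simulate_parents(toy_genome(snp_density = 0.2, min_spacing = 10)),
               "incompatible")
})

test_that("simulated SNP count matches the expected density at genome scale", {
  g <- genome_spec(scale = "full")
  s <- simulate_parents(g, seed = 3)
  expected <- sum(g$chrom$length) * g$snp_density  # ~182,770
  expect_lt(abs(nrow(s) - expected) / expected, 0.02)
})

test_that("panel simulation reproduces Mendelian structure", {
  g <- toy_genome(n_chrom = 2, len = 2e6)
  # no meiosis at all: every line fully heterozygous
  f1 <- simulate_panel(g, breeding_scheme(n_backcross = 0, n_selfing = 0,
                                          n_il = 4), seed = 5)
  expect_true(all(f1$genotype == "HET"))
  expect_true(all(f1$start == 1))

  # paints partition each chromosome exactly and neighbours differ
  p <- simulate_panel(g, breeding_scheme(n_il = 8), seed = 6)
  by_grp <- split(p, paste(p$il, p$chrom))
  for (blk in by_grp) {
    expect_equal(blk$start[1], 1)
    expect_equal(blk$end[nrow(blk)], 2e6)
    if (nrow(blk) > 1) {
      expect_equal(blk$start[-1], blk$end[-nrow(blk)] + 1)
      expect_true(all(blk$genotype[-1] != blk$genotype[-nrow(blk)]))
    }
  }
  expect_identical(p, simulate_panel(g, breeding_scheme(n_il = 8), seed = 6))
})

test_that("donor fraction and residual heterozygosity follow closed forms", {
  g <- genome_spec(n_chrom = 4, chrom_length = 5e6)
  truth <- simulate_panel(g, breeding_scheme(n_il = 200), seed = 11)
  total <- sum(g$chrom$length)
  per_il <- truth |>
    dplyr::group_by(il) |>
    dplyr::summarise(
      donor = sum((end - start + 1) *
                    c(HOM_P1 = 0, HET = 0.5, HOM_P2 = 1)[genotype]) / total,
      het = sum((end - start + 1) * (genotype == "HET")) / total
    )
  # donor allele fraction: (1/2)^(1 + n_backcross) = 1/16
  se_d <- sd(per_il$donor) / sqrt(nrow(per_il))
  expect_lt(abs(mean(per_il$donor) - 1 / 16), 3 * se_d)
  # heterozygous fraction: (1/2)^n_backcross * (1/2)^n_selfing = 2^-9
  se_h <- sd(per_il$het) / sqrt(nrow(per_il))
  expect_lt(abs(mean(per_il$het) - 2^-9), 3 * se_h)
})

test_that("read simulation matches its sampling model", {
  fix <- sim_small_panel(seed = 21, n_il = 6, len = 2e6)
  rm_ <- read_model()
  obs <- simulate_reads(fix$truth, fix$sites, rm_, seed = 22)
  expect_identical(obs, simulate_reads(fix$truth, fix$sites, rm_, seed = 22))
  # missing fraction = Poisson mass at zero depth, within 3 SE
  miss <- obs$reads_p1 + obs$reads_p2 == 0
  p0 <- exp(-rm_$mean_depth)
  expect_lt(abs(mean(miss) - p0), 3 * sqrt(p0 * (1 - p0) / length(miss)))

  # error-free homozygous truth: all reads carry the true allele
  pure <- tibble::tibble(il = "IL001", chrom = "chr01", start = 1, end = 2e6,
                         genotype = "HOM_P2")
  o2 <- simulate_reads(pure, fix$sites[fix$sites$chrom == "chr01", ],
                       read_model(error_rate = 0), seed = 23)
  expect_true(all(o2$reads_p1 == 0))

  # deep heterozygous truth: P1-read fraction ~ 0.5
  het <- dplyr::mutate(pure, genotype = "HET")
  o3 <- simulate_reads(het, fix$sites[fix$sites$chrom == "chr01", ][1:50, ],
                       read_model(mean_depth = 1000), seed = 24)
  frac <- sum(o3$reads_p1) / sum(o3$reads_p1 + o3$reads_p2)
  n_reads <- sum(o3$reads_p1 + o3$reads_p2)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_reads))

  # truth missing a chromosome with sites is an error
  expect_error(simulate_reads(pure, fix$sites, rm_), "chr02")
})

test_that("phenotype simulation follows the additive model", {
  g <- toy_genome(n_chrom = 1, len = 1e6)
  truth <- dplyr::bind_rows(
    mk_paint("IL001", "chr01", 1e6, numeric(0), "HOM_P1"),
    mk_paint("IL002", "chr01", 1e6, numeric(0), "HET"),
    mk_paint("IL003", "chr01", 1e6, numeric(0), "HOM_P2")
  )
  tm <- trait_model(tibble::tibble(trait = "T", site = "A", mean = 10, sd = 1e-9),
                    tibble::tibble(trait = "T", chrom = "chr01", start = 5e5,
                                   end = 5e5, effect = 2))
  ph <- simulate_phenotypes(truth, tm, seed = 31)
  expect_equal(sort(round(ph$value, 6)), c(8, 10, 12))

  # causal interval spanning a breakpoint names the offending line
  truth2 <- dplyr::bind_rows(
    truth,
    mk_paint("IL004", "chr01", 1e6, 5e5, c("HOM_P1", "HOM_P2"))
  )
  tm2 <- trait_model(tm$traits,
                     tibble::tibble(trait = "T", chrom = "chr01", start = 4e5,
                                    end = 6e5, effect = 2))
  expect_error(simulate_phenotypes(truth2, tm2), "IL004")
})

test_that("a single causal locus at target R2 0.3 is recovered by the scan", {
  g <- genome_spec(n_chrom = 4, chrom_length = 8e6)
  r2_hat <- purrr::map_dbl(1:20, function(rep) {
    truth <- simulate_panel(g, breeding_scheme(n_il = 131), seed = 500 + rep)
    bins <- build_bins(truth, g)
    bg <- bin_genotypes(bins, truth)
    x <- bg$code - 1
    # pick a causal bin with appreciable donor content, deterministically
    carriers <- tapply(x > -1, bg$bin, sum)
    eligible <- as.integer(names(carriers)[carriers >= 8])
    causal <- eligible[(rep %% length(eligible)) + 1]
    xs <- x[bg$bin == causal]
    a <- sqrt(0.3 / 0.7) / sd(xs)  # sigma = 1: a^2 var(x) / (a^2 var(x)+1) = 0.3
    b <- bins[bins$bin == causal, ]
    tm <- trait_model(
      tibble::tibble(trait = "T", site = "A", mean = 0, sd = 1),
      tibble::tibble(trait = "T", chrom = b$chrom, start = b$start,
                     end = b$start, effect = a)
    )
    ph <- simulate_phenotypes(truth, tm, seed = 600 + rep)
    sc <- scan_qtl(bg, ph, bins)
    max(sc$r2, na.rm = TRUE)
  })
  expect_lt(abs(mean(r2_hat) - 0.3), 0.1)
})
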
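# Minimal scan scaffolding: a bin map on one or two chromosomes and a long
# genotype table built directly from a code matrix (rows = lines).
mk_scan_input <- function(codes, chrom = NULL) {
  n_bin <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("chr01", n_bin)
  bins <- tibble::tibble(bin = seq_len(n_bin), chrom = chrom,
                         start = (seq_len(n_bin) - 1) * 1e5 + 1,
                         end = seq_len(n_bin) * 1e5,
                         length = 1e5)
  ils <- sprintf("IL%03d", seq_len(nrow(codes)))
  bg <- tibble::tibble(
    il = rep(ils, each = n_bin),
    bin = rep(seq_len(n_bin), nrow(codes)),
    code = as.integer(t(codes))
  )
  bg$genotype <- c("HOM_P1", "HET", "HOM_P2")[bg$code + 1]
  list(bins = bins, bg = bg, ils = ils)
}

mk_pheno <- function(ils, y, trait = "T", site = "A") {
  tibble::tibble(il = ils, site = site, trait = trait, value = y)
}

test_that("scan statistics equal a least-squares oracle on a 12-line example", {
  codes <- matrix(c(0, 0, 0, 0, 1, 1, 2, 2, 2, 0, 1, 2,
                    0, 2, 0, 2, 0, 2, 0, 2, 0, 2, 0, 2), ncol = 2)
  inp <- mk_scan_input(codes)
  y <- c(9.1, 10.2, 8.7, 9.9, 11.5, 10.8, 13.0, 12.1, 13.4, 9.5, 11.2, 12.8)
  scan <- scan_qtl(inp$bg, mk_pheno(inp$ils, y), inp$bins)
  for (b in 1:2) {
    x <- codes[, b] - 1
    fit <- lm(y ~ x)
    sm <- summary(fit)
    row <- scan[scan$bin == b, ]
    expect_equal(row$additive, unname(coef(fit)[2]), tolerance = 1e-9)
    expect_equal(row$r2, sm$r.squared, tolerance = 1e-9)
    expect_equal(row$lod, -length(y) / 2 * log10(1 - sm$r.squared),
                 tolerance = 1e-9)
    expect_equal(row$n, length(y))
  }
})

test_that("degenerate scans behave as documented", {
  codes <- cbind(c(0, 0, 1, 1, 2, 2), rep(0, 6), c(2, 2, 1, 1, 0, 0))
  inp <- mk_scan_input(codes)

  # identical group means: LOD = 0, R2 = 0
  y0 <- c(5, 7, 5, 7, 5, 7)
  s0 <- scan_qtl(inp$bg, mk_pheno(inp$ils, y0), inp$bins)
  expect_equal(s0$lod[s0$bin == 1], 0)
  expect_equal(s0$r2[s0$bin == 1], 0)

  # constant phenotype: LOD 0 everywhere (monomorphic bins stay NA)
  sc <- scan_qtl(inp$bg, mk_pheno(inp$ils, rep(4, 6)), inp$bins)
  expect_equal(sc$lod[sc$bin != 2], c(0, 0))
  expect_true(is.na(sc$lod[sc$bin == 2]))
  expect_equal(sc$note[sc$bin == 2], "monomorphic")

  # too few lines is an error
  tiny <- mk_scan_input(matrix(c(0, 2), ncol = 1))
  expect_error(scan_qtl(tiny$bg, mk_pheno(tiny$ils, c(1, 2)), tiny$bins),
               "fewer than 3")
})

test_that("LOD is invariant under affine phenotype rescaling", {
  set.seed(31)
  codes <- matrix(sample(0:2, 60, replace = TRUE), ncol = 5)
  inp <- mk_scan_input(codes)
  y <- rnorm(12)
  s1 <- scan_qtl(inp$bg, mk_pheno(inp$ils, y), inp$bins)
  s2 <- scan_qtl(inp$bg, mk_pheno(inp$ils, 3 * y + 7), inp$bins)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-12)
  expect_equal(s1$r2, s2$r2, tolerance = 1e-12)
  expect_equal(3 * s1$additive, s2$additive, tolerance = 1e-12)
})

# Hand-assembled scan object for the QTL-calling rules.
mk_scan_obj <- function(df, bins) {
  df$n <- 10L
  df$r2 <- 0.2
  df$additive <- 1
  df$note <- NA_character_
  attr(df, "bins") <- bins
  class(df) <- c("il_scan", class(df))
  df
}

test_that("QTL calling groups contiguous significant bins and merges sites", {
  bins <- tibble::tibble(bin = 1:20, chrom = rep(c("chr01", "chr02"), each = 10),
                         start = rep((0:9) * 1e5 + 1, 2),
                         end = rep((1:10) * 1e5, 2), length = 1e5)
  base <- tidyr::expand_grid(trait = "T", site = c("A", "B"), bin = 1:20) |>
    dplyr::mutate(chrom = bins$chrom[bin], lod = 0.5)

  # nothing significant: empty result
  empty <- call_qtls(mk_scan_obj(base, bins))
  expect_equal(nrow(empty), 0)

  # two runs separated by a sub-threshold bin: two QTLs
  two <- base
  two$lod[two$site == "A" & two$bin %in% c(3, 4, 6)] <- 3
  q2 <- call_qtls(mk_scan_obj(two, bins))
  expect_equal(nrow(q2), 2)
  expect_false(any(q2$both_sites))

  # site-A run {10..12} and site-B run {12..13} share bin 12: one QTL
  ## (bins 10-12 sit on chr01/chr02 boundary; use 14..16 and 16..17 instead)
  ov <- base
  ov$lod[ov$site == "A" & ov$bin %in% 14:16] <- c(2.5, 4, 3)
  ov$lod[ov$site == "B" & ov$bin %in% 16:17] <- 2.2
  q3 <- call_qtls(mk_scan_obj(ov, bins))
  expect_equal(nrow(q3), 1)
  expect_true(q3$both_sites)
  expect_equal(q3$peak_bin, 15)  # site-A max
  expect_equal(sort(unlist(q3$support_bins)), 14:17)
  ss <- q3$site_stats[[1]]
  expect_equal(sort(ss$site), c("A", "B"))
  expect_equal(ss$peak_bin[ss$site == "B"], 16)

  # peak tie goes to the smaller bin id
  tie <- base
  tie$lod[tie$site == "A" & tie$bin %in% 4:5] <- 3
  expect_equal(call_qtls(mk_scan_obj(tie, bins))$peak_bin, 4)
})

test_that("QTL names follow the q + trait + chromosome convention", {
  q <- tibble::tibble(
    trait = c("PH", "GL", "GL", "PH"),
    chrom = c("chr01", "chr03", "chr03", "chr03"),
    peak_bin = c(10L, 40L, 31L, 35L)
  )
  named <- name_qtls(q)
  expect_equal(named$name, c("qPH1", "qGL3.2", "qGL3.1", "qPH3"))
  expect_equal(nrow(name_qtls(q[0, ])), 0)
})

test_that("trait correlations match the closed-form Pearson formula", {
  ph <- dplyr::bind_rows(
    mk_pheno(sprintf("IL%03d", 1:5), c(1, 2, 3, 4, 5), trait = "X"),
    mk_pheno(sprintf("IL%03d", 1:5), c(2, 1, 4, 3, 6), trait = "Y"),
    mk_pheno(sprintf("IL%03d", 1:5), c(-1, -2, -3, -4, -5), trait = "Z")
  )
  ct <- correlate_traits(ph, "A")
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r[ct$trait1 == "X" & ct$trait2 == "Y"], r_hand)
  expect_equal(ct$r[ct$trait1 == "X" & ct$trait2 == "Z"], -1)
  expect_true(ct$significant[ct$trait1 == "X" & ct$trait2 == "Z"])

  # constant trait reported as missing with a reason
  ph2 <- dplyr::bind_rows(ph, mk_pheno(sprintf("IL%03d", 1:5), rep(1, 5),
                                       trait = "C"))
  ct2 <- correlate_traits(ph2, "A")
  expect_true(is.na(ct2$r[ct2$trait2 == "C" & ct2$trait1 == "X"]))
  expect_equal(ct2$note[ct2$trait2 == "C" & ct2$trait1 == "X"],
               "constant trait")
})

test_that("transgressive screening applies strict/inclusive margins per site", {
  ph <- tibble::tibble(
    il = rep(c("IL001", "IL002", "IL003", "IL004"), each = 2),
    site = rep(c("A", "B"), 4),
    trait = "YPP",
    value = c(110, 110,      # exactly +10%: NOT superior (strict >)
              110.5, 111,    # above +10% at both: superior
              85, 85,        # exactly -15% at both: inferior (inclusive)
              120, 100)      # superior at one site only: neither
  )
  parents <- tibble::tibble(site = c("A", "B"), value = c(100, 100))
  tg <- transgressive_lines(ph, "YPP", parents)
  expect_equal(tg$il, c("IL002", "IL003"))
  expect_equal(tg$status, c("superior", "inferior"))
  expect_error(transgressive_lines(ph, "YPP", parents[1, ]), "site")
})

test_that("with no causal effects the genome-wide scan rarely reaches LOD 2", {
  g <- genome_spec(n_chrom = 6, chrom_length = 10e6)
  hits <- purrr::map_lgl(1:12, function(rep) {
    truth <- simulate_panel(g, breeding_scheme(n_il = 131), seed = 7000 + rep)
    bins <- build_bins(truth, g)
    bg <- bin_genotypes(bins, truth)
    tm <- trait_model(tibble::tibble(trait = "T", site = "A", mean = 0, sd = 1))
    ph <- simulate_phenotypes(truth, tm, seed = 7100 + rep)
    sc <- scan_qtl(bg, ph, bins)
    max(sc$lod, na.rm = TRUE) >= 2
  })
  expect_lt(sum(hits), 6)  # a minority of replicates
})

test_that("null LOD exceedance matches the chi-squared approximation", {
  set.seed(99)
  n <- 131
  n_bins <- 40000
  codes <- matrix(sample(0:2, n * n_bins, replace = TRUE,
                         prob = c(0.9, 0.02, 0.08)), nrow = n)
  y <- rnorm(n)
  x <- codes - 1
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  r2 <- (colSums(xc * yc))^2 / (sxx * sum(yc^2))
  lod <- -n / 2 * log10(1 - r2)
  rate <- mean(lod >= 2)
  p_chi2 <- pchisq(2 * 2 * log(10), df = 1, lower.tail = FALSE)
  expect_lt(abs(rate - p_chi2), 0.001)
})
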
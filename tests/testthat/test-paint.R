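test_that("per-SNP calls are majority with ties missing", {
  obs <- tibble::tibble(il = "IL001", chrom = "chr01", pos = 1:4 * 100,
                        reads_p1 = c(3L, 2L, 1L, 0L),
                        reads_p2 = c(0L, 2L, 2L, 0L))
  expect_equal(call_snps(obs)$call, c("P1", "MISSING", "P2", "MISSING"))
})

test_that("kNN imputation fills gaps by nearest-neighbour majority", {
  # a missing site flanked by five P2 calls becomes P2
  calls <- mk_calls(c("P2", "P2", "MISSING", "P2", "P2", "P2"))
  out <- impute_calls(calls, k = 5)
  expect_false(any(out$call == "MISSING"))
  expect_equal(out$call[3], "P2")

  # tied vote (even k) follows the single nearest neighbour
  calls2 <- mk_calls(c("P2", "MISSING", "P1", "P2", "P1"),
                     pos = c(900, 1000, 1200, 1300, 1500))
  expect_equal(impute_calls(calls2, k = 4)$call[2], "P2")

  # a chromosome with no usable call names the line
  calls3 <- mk_calls(c("MISSING", "MISSING"))
  expect_error(impute_calls(calls3), "IL001")
})

test_that("imputed calls recover the truth away from breakpoints", {
  fix <- sim_small_panel(seed = 61, n_il = 6, n_chrom = 2, len = 5e6)
  obs <- simulate_reads(fix$truth, fix$sites, read_model(), seed = 62)
  imputed <- impute_calls(call_snps(obs))
  truth_split <- split(fix$truth, paste(fix$truth$il, fix$truth$chrom))
  scored <- imputed |>
    dplyr::group_by(il, chrom) |>
    dplyr::group_modify(function(df, key) {
      blk <- truth_split[[paste(key$il, key$chrom)]]
      code <- c(HOM_P1 = 0, HET = 1, HOM_P2 = 2)[blk$genotype]
      truth_code <- code[findInterval(df$pos - 0.5, blk$end) + 1]
      bp <- blk$end[-nrow(blk)]
      near_bp <- if (length(bp) == 0) rep(FALSE, nrow(df)) else
        vapply(df$pos, function(p) min(abs(bp - p)) < 1e5, logical(1))
      # away from breakpoints a homozygous call must match the truth allele
      hom <- truth_code != 1 & !near_bp
      tibble::tibble(ok = (df$call[hom] == ifelse(truth_code[hom] == 0, "P1", "P2")))
    })
  expect_gte(mean(scored$ok), 0.95)
})

test_that("window classification follows the 14:3 / 5:12 thresholds exactly", {
  n1 <- 0:17
  got <- classify_window(n1, 17 - n1)
  expect_equal(got, ifelse(n1 >= 14, "HOM_P1", ifelse(n1 <= 5, "HOM_P2", "HET")))
  # printed boundary cases
  expect_equal(classify_window(14, 3), "HOM_P1")
  expect_equal(classify_window(5, 12), "HOM_P2")
  expect_equal(classify_window(17, 0), "HOM_P1")
  expect_equal(classify_window(6, 11), "HET")
  expect_equal(classify_window(13, 4), "HET")
  # monotonicity: more recipient calls never moves towards the donor call
  code <- c(HOM_P1 = 0, HET = 1, HOM_P2 = 2)[got]
  expect_true(all(diff(code) <= 0))
  expect_error(classify_window(10, 8), "sum")
})

test_that("painting merges windows into blocks with midpoint breakpoints", {
  g <- toy_genome(n_chrom = 1, len = 250000)
  # uniform calls: one block, no breakpoints
  uni <- mk_calls(rep("P1", 30), pos = 1:30 * 1000)
  p_uni <- paint_panel(uni, g)
  expect_equal(nrow(p_uni), 1)
  expect_equal(c(p_uni$start, p_uni$end, p_uni$genotype),
               c("1", "250000", "HOM_P1"))

  # 100 P1 then 100 P2 at 1 kb spacing, evaluated by hand:
  # windows 1..87 HOM_P1 (n1 >= 14), 88..95 HET, 96..184 HOM_P2;
  # transitions between window centres 95/96 and 103/104
  calls <- mk_calls(rep(c("P1", "P2"), each = 100), pos = 1:200 * 1000)
  p <- paint_panel(calls, g)
  expect_equal(p$genotype, c("HOM_P1", "HET", "HOM_P2"))
  expect_equal(p$end, c(95500, 103500, 250000))
  bp <- paint_breakpoints(p)
  expect_equal(bp$pos, c(95500, 103500))
  expect_equal(nrow(bp), nrow(p) - 1)

  # blocks partition the chromosome
  expect_equal(p$start, c(1, p$end[-3] + 1))
})

test_that("chromosomes with fewer sites than a window fall back to majority", {
  g <- toy_genome(n_chrom = 1, len = 1e5)
  few <- mk_calls(c(rep("P2", 7), rep("P1", 3)), pos = 1:10 * 1000)
  expect_warning(p <- paint_panel(few, g), "fewer than 17")
  expect_equal(nrow(p), 1)
  expect_equal(p$genotype, "HOM_P2")
})

test_that("block smoothing absorbs short runs", {
  g <- toy_genome(n_chrom = 1, len = 2e5)
  # one isolated P2 stretch too short to flip more than a few windows
  calls <- mk_calls(c(rep("P1", 60), rep("P2", 13), rep("P1", 60)),
                    pos = 1:133 * 1000)
  raw <- paint_panel(calls, g)
  sm <- paint_panel(calls, g, min_block_windows = 24)
  expect_gt(nrow(raw), 1)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$genotype, "HOM_P1")
})

test_that("crossover counts recount breakpoints exactly", {
  paints <- dplyr::bind_rows(
    mk_paint("IL001", "chr01", 1e6, c(2e5, 6e5), c("HOM_P1", "HOM_P2", "HOM_P1")),
    mk_paint("IL001", "chr02", 1e6, numeric(0), "HOM_P1"),
    mk_paint("IL002", "chr01", 1e6, 5e5, c("HOM_P1", "HET")),
    mk_paint("IL002", "chr02", 1e6, numeric(0), "HOM_P2")
  )
  co <- count_crossovers(paints)
  expect_equal(co$total, 3)
  expect_equal(co$per_il$n_co, c(2L, 1L))
  expect_equal(co$mean_per_il, 1.5)
  expect_equal(co$per_chrom$n_co, c(3L, 0L))
  # independent recount
  expect_equal(co$total, nrow(paint_breakpoints(paints)))

  single <- dplyr::filter(paints, il == "IL001", chrom == "chr02")
  expect_equal(count_crossovers(single)$total, 0)
})

test_that("painting a simulated panel is deterministic end to end", {
  fix <- sim_small_panel(seed = 71, n_il = 4, n_chrom = 1, len = 3e6)
  obs <- simulate_reads(fix$truth, fix$sites, read_model(), seed = 72)
  run <- function() paint_panel(impute_calls(call_snps(obs)), fix$genome)
  expect_identical(run(), run())
})
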
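#' Per-SNP genotype calls from allele read counts
#'
#' The majority allele wins; ties (including zero depth) are `MISSING`.
#'
#' @param obs Observation tibble with `il`, `chrom`, `pos`, `reads_p1`,
#'   `reads_p2`.
#' @return Tibble `il`, `chrom`, `pos`, `call` with call in
#'   `P1`/`P2`/`MISSING`.
#' @export
call_snps <- function(obs) {
  stopifnot(all(obs$reads_p1 >= 0), all(obs$reads_p2 >= 0))
  tibble::tibble(
    il = obs$il, chrom = obs$chrom, pos = obs$pos,
    call = dplyr::case_when(
      obs$reads_p1 > obs$reads_p2 ~ "P1",
      obs$reads_p2 > obs$reads_p1 ~ "P2",
      TRUE ~ "MISSING"
    )
  )
}

## k-nearest-neighbour imputation on one chromosome of one line.
## pos: sorted positions; call_int: 1 = P1, 2 = P2, NA = missing.
.impute_chr <- function(pos, call_int, k) {
  miss <- which(is.na(call_int))
  if (length(miss) == 0) return(call_int)
  obs <- which(!is.na(call_int))
  po <- pos[obs]
  co <- call_int[obs]
  kk <- min(k, length(obs))
  j <- findInterval(pos[miss], po)
  for (t in seq_along(miss)) {
    lo <- max(1L, j[t] - kk + 1L)
    hi <- min(length(obs), j[t] + kk)
    cand <- lo:hi
    d <- abs(po[cand] - pos[miss][t])
    ## deterministic order: distance, then leftmost position
    sel <- cand[order(d, po[cand])][seq_len(kk)]
    n2 <- sum(co[sel] == 2L)
    call_int[miss[t]] <- if (2L * n2 > kk) 2L
    else if (2L * n2 < kk) 1L
    else co[sel[1L]]  # tie: follow the physically nearest neighbour
  }
  call_int
}

#' Impute missing per-SNP calls by k nearest neighbours
#'
#' Each `MISSING` call is replaced by the majority among the `k` non-missing
#' calls nearest in physical distance on the same chromosome of the same line;
#' a tied vote follows the single nearest neighbour. A line with no
#' non-missing call on a chromosome is an error naming the line.
#'
#' @param calls Output of [call_snps()].
#' @param k Number of neighbours (default 5).
#' @return The call tibble with no `MISSING` entries.
#' @export
impute_calls <- function(calls, k = 5) {
  stopifnot(k >= 1)
  calls |>
    dplyr::group_by(.data$il, .data$chrom) |>
    dplyr::group_modify(function(df, key) {
      o <- order(df$pos)
      ci <- c(P1 = 1L, P2 = 2L)[df$call[o]]
      if (all(is.na(ci)))
        stop("no non-missing calls for ", key$il, " on ", key$chrom,
             "; cannot impute", call. = FALSE)
      ci <- .impute_chr(df$pos[o], unname(ci), k)
      tibble::tibble(pos = df$pos[o], call = c("P1", "P2")[ci])
    }) |>
    dplyr::ungroup()
}

#' Classify a sliding window by its recipient:donor call ratio
#'
#' With the default 17-SNP window, a recipient:donor ratio of 14:3 or higher
#' is a homozygous-recipient window, 5:12 or lower a homozygous-donor window,
#' and anything between is heterozygous.
#'
#' @param n1,n2 Counts of recipient (P1) and donor (P2) calls; vectorised.
#'   Must sum to `window_size`.
#' @param window_size Window size in SNPs (default 17).
#' @param hom1_min Minimum P1 count for a homozygous-recipient call (default 14).
#' @param hom2_max Maximum P1 count for a homozygous-donor call (default 5).
#' @return Character vector of `HOM_P1`/`HET`/`HOM_P2`.
#' @export
#' @examples
#' classify_window(14, 3)  # "HOM_P1"
#' classify_window(5, 12)  # "HOM_P2"
#' classify_window(6, 11)  # "HET"
classify_window <- function(n1, n2, window_size = 17, hom1_min = 14,
                            hom2_max = 5) {
  if (any(n1 < 0 | n2 < 0)) stop("window counts must be >= 0")
  if (any(n1 + n2 != window_size))
    stop("window counts must sum to the window size (", window_size, ")")
  dplyr::case_when(
    n1 >= hom1_min ~ "HOM_P1",
    n1 <= hom2_max ~ "HOM_P2",
    TRUE ~ "HET"
  )
}

## Reassign windows of runs shorter than min_run to the larger neighbouring
## run (left on ties) until every run is at least min_run windows long.
.smooth_runs <- function(g, min_run) {
  repeat {
    r <- rle(g)
    if (length(r$lengths) <= 1L || all(r$lengths >= min_run)) return(g)
    i <- which(r$lengths < min_run)[1L]
    target <- if (i == 1L) 2L
    else if (i == length(r$lengths)) i - 1L
    else if (r$lengths[i + 1L] > r$lengths[i - 1L]) i + 1L
    else i - 1L
    r$values[i] <- r$values[target]
    g <- inverse.rle(r)
  }
}

## Paint one chromosome of one line from imputed calls.
.paint_chr <- function(pos, call_int, L, window_size, hom1_min, hom2_max,
                       min_block_windows, label = "") {
  m <- length(pos)
  if (m < window_size) {
    n1 <- sum(call_int == 1L)
    g <- if (n1 > m - n1) "HOM_P1" else if (n1 < m - n1) "HOM_P2" else "HET"
    warning("fewer than ", window_size, " sites on ", label,
            "; painted as a single ", g, " block", call. = FALSE)
    return(tibble::tibble(start = 1, end = L, genotype = g))
  }
  cs <- c(0L, cumsum(call_int == 1L))
  n1 <- cs[(window_size + 1L):(m + 1L)] - cs[seq_len(m - window_size + 1L)]
  g <- ifelse(n1 >= hom1_min, 0L, ifelse(n1 <= hom2_max, 2L, 1L))
  if (min_block_windows > 0) g <- .smooth_runs(g, min_block_windows)
  r <- rle(g)
  run_end <- cumsum(r$lengths)
  c0 <- (window_size - 1L) %/% 2L  # central SNP offset from window start
  if (length(run_end) > 1L) {
    t <- run_end[-length(run_end)]
    bp <- floor((pos[t + c0] + pos[t + 1L + c0]) / 2)
  } else {
    bp <- numeric(0)
  }
  tibble::tibble(start = c(1, bp + 1), end = c(bp, L),
                 genotype = geno_label(r$values))
}

#' Paint chromosome mosaics by the sliding-window method
#'
#' Slides a `window_size`-SNP window in 1-SNP steps over each line's imputed
#' calls, classifies every fully supported window with [classify_window()],
#' merges consecutive equal-genotype windows into blocks, and places one
#' recombination breakpoint per block transition at the midpoint between the
#' central SNPs of the two flanking windows. End blocks are extended to the
#' chromosome boundaries. A chromosome with fewer sites than the window is
#' painted as a single block of the majority per-SNP call, with a warning.
#'
#' @param calls Imputed calls from [impute_calls()] (no `MISSING`).
#' @param genome A [genome_spec()] giving chromosome lengths.
#' @param window_size,hom1_min,hom2_max See [classify_window()].
#' @param min_block_windows Optional smoothing: blocks spanning fewer windows
#'   than this are absorbed into their larger neighbour (default 0 = off).
#' @return Paint tibble `il`, `chrom`, `start`, `end`, `genotype`; blocks
#'   partition each chromosome and adjacent blocks differ in genotype.
#' @export
paint_panel <- function(calls, genome, window_size = 17, hom1_min = 14,
                        hom2_max = 5, min_block_windows = 0) {
  stopifnot(inherits(genome, "genome_spec"))
  if (any(calls$call == "MISSING"))
    stop("calls contain MISSING entries; run impute_calls() first")
  lens <- stats::setNames(genome$chrom$length, genome$chrom$chrom)
  calls |>
    dplyr::group_by(.data$il, .data$chrom) |>
    dplyr::group_modify(function(df, key) {
      L <- lens[[key$chrom]]
      if (is.null(L)) stop("chromosome ", key$chrom, " not in genome spec")
      o <- order(df$pos)
      .paint_chr(df$pos[o], c(P1 = 1L, P2 = 2L)[df$call[o]], L,
                 window_size, hom1_min, hom2_max, min_block_windows,
                 label = paste0(key$il, "/", key$chrom))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("il", "chrom", "start", "end", "genotype")
}

#' Recombination breakpoints implied by a paint
#'
#' One breakpoint per adjacent block pair: its position is the end of the left
#' block (blocks are 1-based inclusive, so the right block starts at pos + 1).
#'
#' @param paints A paint tibble (inferred or truth).
#' @return Tibble `il`, `chrom`, `pos`, `left`, `right`.
#' @export
paint_breakpoints <- function(paints) {
  paints |>
    dplyr::group_by(.data$il, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(
      pos = .data$end[-dplyr::n()],
      left = .data$genotype[-dplyr::n()],
      right = .data$genotype[-1]
    )
}

#' Crossover counts per line, per chromosome, and in total
#'
#' Counts detected breakpoints (block transitions) as crossover events.
#'
#' @param paints A paint tibble.
#' @return List with `per_il` (tibble `il`, `n_co`; lines with none included),
#'   `per_chrom` (tibble `chrom`, `n_co`), `total`, and `mean_per_il`.
#' @export
count_crossovers <- function(paints) {
  bp <- paint_breakpoints(paints)
  ils <- sort(unique(paints$il))
  per_il <- tibble::tibble(il = ils) |>
    dplyr::left_join(dplyr::count(bp, .data$il, name = "n_co"), by = "il") |>
    dplyr::mutate(n_co = dplyr::coalesce(.data$n_co, 0L))
  per_chrom <- tibble::tibble(chrom = sort(unique(paints$chrom))) |>
    dplyr::left_join(dplyr::count(bp, .data$chrom, name = "n_co"), by = "chrom") |>
    dplyr::mutate(n_co = dplyr::coalesce(.data$n_co, 0L))
  list(per_il = per_il, per_chrom = per_chrom,
       total = nrow(bp), mean_per_il = nrow(bp) / length(ils))
}

#' Genotype accuracy of inferred paints against ground truth
#'
#' Compares the inferred genotype of every (line, bin) cell with the truth
#' genotype at the bin midpoint.
#'
#' @param paints Inferred paints.
#' @param truth Truth paints from [simulate_panel()].
#' @param bins Bin table from [build_bins()] on the inferred paints.
#' @return List with `accuracy` (overall proportion correct) and `by_il`.
#' @export
paint_accuracy <- function(paints, truth, bins) {
  bg <- bin_genotypes(bins, paints)
  bg <- dplyr::left_join(bg,
                         dplyr::select(bins, "bin", "start", "end"), by = "bin")
  mid <- floor((bg$start + bg$end) / 2)
  truth_split <- split(truth, paste(truth$il, truth$chrom, sep = "\r"))
  key <- paste(bg$il,
               bins$chrom[match(bg$bin, bins$bin)], sep = "\r")
  truth_geno <- vapply(seq_len(nrow(bg)), function(i) {
    blk <- truth_split[[key[i]]]
    geno_label(.code_at(blk$end, geno_code(blk$genotype), mid[i]))
  }, character(1))
  ok <- bg$genotype == truth_geno
  list(
    accuracy = mean(ok),
    by_il = tibble::tibble(il = bg$il, ok = ok) |>
      dplyr::group_by(.data$il) |>
      dplyr::summarise(accuracy = mean(.data$ok))
  )
}

#' Breakpoint localisation against true crossovers
#'
#' Matches every true genotype transition to the nearest inferred breakpoint
#' of the same line and chromosome.
#'
#' @param paints Inferred paints.
#' @param truth Truth paints.
#' @param tol_bp Maximum distance for a transition to count as recovered
#'   (default 200 kb).
#' @return List with `recall` (fraction of true transitions with an inferred
#'   breakpoint within `tol_bp`) and `distances` (per-transition tibble; the
#'   distance is `Inf` where a line/chromosome has no inferred breakpoint).
#' @export
breakpoint_recall <- function(paints, truth, tol_bp = 2e5) {
  tb <- paint_breakpoints(truth)
  ib <- paint_breakpoints(paints)
  if (nrow(tb) == 0) return(list(recall = NA_real_, distances = tb))
  ib_split <- split(ib$pos, paste(ib$il, ib$chrom, sep = "\r"))
  key <- paste(tb$il, tb$chrom, sep = "\r")
  dist <- vapply(seq_len(nrow(tb)), function(i) {
    cand <- ib_split[[key[i]]]
    if (is.null(cand)) Inf else min(abs(cand - tb$pos[i]))
  }, numeric(1))
  list(recall = mean(dist <= tol_bp),
       distances = dplyr::mutate(tb, dist = dist))
}
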
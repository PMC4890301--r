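#' Bin-marker QTL scan by single-marker regression
#'
#' Per bin, trait, and site, fits least squares `y = b0 + b1 x` with additive
#' coding `x = -1/0/+1` for recipient-homozygous / heterozygous /
#' donor-homozygous lines, and reports `LOD = (n/2) log10(RSS0/RSS1)`,
#' `R^2 = 1 - RSS1/RSS0`, and the additive effect `b1` (positive means the
#' donor allele increases the trait). Monomorphic bins are retained with NA
#' statistics and a note; a site/trait combination with a constant phenotype
#' scores LOD 0 everywhere.
#'
#' @param bin_geno Long genotype table from [bin_genotypes()].
#' @param pheno Phenotype tibble `il`, `site`, `trait`, `value`.
#' @param bins Bin table from [build_bins()] (carried for coordinates).
#' @param traits,sites Optional subsets; default all present in `pheno`.
#' @return An `il_scan` tibble: `trait`, `site`, `bin`, `chrom`, `n`, `lod`,
#'   `r2`, `additive`, `note`, with the bin table attached as an attribute.
#' @export
scan_qtl <- function(bin_geno, pheno, bins, traits = NULL, sites = NULL) {
  combos <- dplyr::distinct(pheno, .data$trait, .data$site)
  if (!is.null(traits)) combos <- combos[combos$trait %in% traits, ]
  if (!is.null(sites)) combos <- combos[combos$site %in% sites, ]
  X <- bin_matrix(bin_geno) - 1L
  bin_ids <- as.integer(colnames(X))
  chrom_of <- bins$chrom[match(bin_ids, bins$bin)]
  res <- purrr::pmap_dfr(combos, function(trait, site) {
    ph <- pheno[pheno$trait == trait & pheno$site == site & !is.na(pheno$value), ]
    ids <- intersect(rownames(X), ph$il)
    n <- length(ids)
    if (n < 3)
      stop("fewer than 3 lines with phenotype and genotype for ",
           trait, " at ", site)
    y <- ph$value[match(ids, ph$il)]
    x <- X[ids, , drop = FALSE]
    xc <- sweep(x, 2, colMeans(x))
    yc <- y - mean(y)
    sxx <- colSums(xc^2)
    sxy <- colSums(xc * yc)
    syy <- sum(yc^2)
    mono <- sxx == 0
    beta <- ifelse(mono, NA_real_, sxy / sxx)
    rss1 <- syy - ifelse(mono, 0, sxy^2 / sxx)
    if (syy <= 0) {
      lod <- r2 <- rep(0, length(sxx))
      beta <- rep(0, length(sxx))
      lod[mono] <- r2[mono] <- beta[mono] <- NA_real_
    } else {
      lod <- ifelse(mono, NA_real_,
                    ifelse(rss1 <= 0, Inf, n / 2 * log10(syy / rss1)))
      r2 <- ifelse(mono, NA_real_, 1 - rss1 / syy)
    }
    tibble::tibble(
      trait = trait, site = site, bin = bin_ids, chrom = chrom_of, n = n,
      lod = unname(lod), r2 = unname(r2), additive = unname(beta),
      note = unname(ifelse(mono, "monomorphic", NA_character_))
    )
  })
  attr(res, "bins") <- bins
  class(res) <- c("il_scan", class(res))
  res
}

#' Call QTLs from a scan at a fixed LOD threshold
#'
#' Maximal runs of contiguous bins with `LOD >= lod_threshold` on one
#' chromosome form one site-level QTL (peak = max-LOD bin, ties to the
#' smaller bin id). Runs of the same trait from different sites are merged
#' into one record when their supporting bins share at least one bin; the
#' both-sites flag marks records supported by more than one site.
#'
#' @param scan An [scan_qtl()] result.
#' @param lod_threshold LOD significance threshold (default 2.0).
#' @return An `il_qtl` tibble: `trait`, `chrom`, `peak_bin`, `peak_start`,
#'   `peak_end`, `support_bins` (list), `n_sites`, `both_sites`, and
#'   `site_stats` (list of per-site peak statistics tibbles).
#' @export
call_qtls <- function(scan, lod_threshold = 2) {
  bins <- attr(scan, "bins")
  sig <- scan[!is.na(scan$lod) & scan$lod >= lod_threshold, ]
  if (nrow(sig) == 0) {
    out <- tibble::tibble(
      trait = character(), chrom = character(), peak_bin = integer(),
      peak_start = numeric(), peak_end = numeric(),
      support_bins = list(), n_sites = integer(), both_sites = logical(),
      site_stats = list()
    )
    attr(out, "bins") <- bins
    class(out) <- c("il_qtl", class(out))
    return(out)
  }
  runs <- sig |>
    dplyr::arrange(.data$trait, .data$site, .data$bin) |>
    dplyr::group_by(.data$trait, .data$site, .data$chrom) |>
    dplyr::mutate(run = cumsum(c(1, diff(.data$bin) != 1))) |>
    dplyr::group_by(.data$trait, .data$site, .data$chrom, .data$run) |>
    dplyr::summarise(
      bins = list(.data$bin),
      peak_idx = order(-.data$lod, .data$bin)[1],
      peak_bin = .data$bin[.data$peak_idx[1]],
      peak_lod = .data$lod[.data$peak_idx[1]],
      peak_r2 = .data$r2[.data$peak_idx[1]],
      peak_additive = .data$additive[.data$peak_idx[1]],
      n = .data$n[1],
      .groups = "drop"
    ) |>
    dplyr::select(-"peak_idx") |>
    dplyr::rename(lod = "peak_lod", r2 = "peak_r2", additive = "peak_additive")
  ## merge overlapping runs across sites within trait x chromosome
  out <- runs |>
    dplyr::group_by(.data$trait, .data$chrom) |>
    dplyr::group_modify(function(df, key) {
      k <- nrow(df)
      grp <- seq_len(k)
      repeat {
        changed <- FALSE
        for (i in seq_len(k)) for (j in seq_len(k)) {
          if (grp[i] != grp[j] &&
              length(intersect(df$bins[[i]], df$bins[[j]])) > 0) {
            grp[grp == grp[j]] <- grp[i]
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      purrr::map_dfr(unique(grp), function(g) {
        sub <- df[grp == g, ]
        best <- order(-sub$lod, sub$peak_bin)[1]
        tibble::tibble(
          peak_bin = sub$peak_bin[best],
          support_bins = list(sort(unique(unlist(sub$bins)))),
          n_sites = dplyr::n_distinct(sub$site),
          both_sites = dplyr::n_distinct(sub$site) >= 2,
          site_stats = list(dplyr::select(sub, "site", "peak_bin", "lod",
                                          "r2", "additive", "n"))
        )
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      peak_start = bins$start[match(.data$peak_bin, bins$bin)],
      peak_end = bins$end[match(.data$peak_bin, bins$bin)]
    ) |>
    dplyr::select("trait", "chrom", "peak_bin", "peak_start", "peak_end",
                  "support_bins", "n_sites", "both_sites", "site_stats") |>
    dplyr::arrange(.data$chrom, .data$peak_bin, .data$trait)
  attr(out, "bins") <- bins
  class(out) <- c("il_qtl", class(out))
  out
}

#' Name QTLs by trait, chromosome, and genome order
#'
#' Names follow the standard rice nomenclature: `q` + trait code + chromosome
#' number, with `.1`, `.2`, ... suffixes in genome order when one trait has
#' several QTLs on a chromosome (e.g. `qGL3.1`, `qGL3.2`).
#'
#' @param qtls A QTL table with `trait`, `chrom`, `peak_bin` columns
#'   (typically from [call_qtls()]).
#' @return The input with a `name` column added (unique).
#' @export
name_qtls <- function(qtls) {
  if (nrow(qtls) == 0) return(dplyr::mutate(qtls, name = character(0)))
  chrom_num <- sub("^0+", "", gsub("[^0-9]", "", qtls$chrom))
  named <- tibble::tibble(i = seq_len(nrow(qtls)), trait = qtls$trait,
                          chrom_num = chrom_num, peak_bin = qtls$peak_bin) |>
    dplyr::group_by(.data$trait, .data$chrom_num) |>
    dplyr::arrange(.data$peak_bin, .by_group = TRUE) |>
    dplyr::mutate(name = if (dplyr::n() == 1) {
      paste0("q", .data$trait, .data$chrom_num)
    } else {
      paste0("q", .data$trait, .data$chrom_num, ".", dplyr::row_number())
    }) |>
    dplyr::ungroup()
  qtls$name <- named$name[order(named$i)]
  stopifnot(!anyDuplicated(qtls$name))
  qtls
}

#' Pairwise Pearson correlations between traits at one site
#'
#' @param pheno Phenotype tibble `il`, `site`, `trait`, `value`.
#' @param site Site (environment) to correlate within.
#' @param alpha Significance flag threshold (default 0.05).
#' @return Tibble `trait1`, `trait2`, `n`, `r`, `p`, `significant`, `note`;
#'   pairs with fewer than 3 complete observations or a constant trait are
#'   reported with NA and a reason.
#' @export
correlate_traits <- function(pheno, site, alpha = 0.05) {
  wide <- pheno[pheno$site == site, c("il", "trait", "value")] |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  traits <- setdiff(names(wide), "il")
  pairs <- utils::combn(traits, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    t1 <- pairs[1, k]; t2 <- pairs[2, k]
    ok <- !is.na(wide[[t1]]) & !is.na(wide[[t2]])
    x <- wide[[t1]][ok]; y <- wide[[t2]][ok]
    if (sum(ok) < 3)
      return(tibble::tibble(trait1 = t1, trait2 = t2, n = sum(ok),
                            r = NA_real_, p = NA_real_, significant = NA,
                            note = "fewer than 3 complete pairs"))
    if (sd(x) == 0 || sd(y) == 0)
      return(tibble::tibble(trait1 = t1, trait2 = t2, n = sum(ok),
                            r = NA_real_, p = NA_real_, significant = NA,
                            note = "constant trait"))
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(trait1 = t1, trait2 = t2, n = sum(ok),
                   r = unname(ct$estimate), p = ct$p.value,
                   significant = ct$p.value < alpha, note = NA_character_)
  })
}

#' Screen for transgressive lines against the recurrent parent
#'
#' Superior lines exceed the recurrent parent by more than `superior_margin`
#' at every site (strict); inferior lines fall at least `inferior_margin`
#' below it at every site (inclusive).
#'
#' @param pheno Phenotype tibble `il`, `site`, `trait`, `value`.
#' @param trait Trait to screen (default yield per plant, `"YPP"`).
#' @param parent_values Tibble `site`, `value` with the recurrent parent's
#'   trait value per site; a site lacking a parent value is an error.
#' @param superior_margin,inferior_margin Fractional margins (defaults 0.10
#'   and 0.15).
#' @return Tibble `il`, `status` (`superior`/`inferior`) for flagged lines.
#' @export
transgressive_lines <- function(pheno, trait = "YPP", parent_values,
                                superior_margin = 0.10, inferior_margin = 0.15) {
  ph <- pheno[pheno$trait == trait & !is.na(pheno$value), ]
  sites <- unique(ph$site)
  missing <- setdiff(sites, parent_values$site)
  if (length(missing) > 0)
    stop("missing recurrent-parent value for site(s): ",
         paste(missing, collapse = ", "))
  pv <- stats::setNames(parent_values$value, parent_values$site)
  ph |>
    dplyr::group_by(.data$il) |>
    dplyr::summarise(
      complete = dplyr::n_distinct(.data$site) == length(sites),
      superior = .data$complete[1] &&
        all(.data$value > (1 + superior_margin) * pv[.data$site]),
      inferior = .data$complete[1] &&
        all(.data$value <= (1 - inferior_margin) * pv[.data$site])
    ) |>
    dplyr::filter(.data$superior | .data$inferior) |>
    dplyr::transmute(.data$il,
                     status = ifelse(.data$superior, "superior", "inferior"))
}
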
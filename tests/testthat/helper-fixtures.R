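# Shared fixture builders: everything is generated in code at test time.

toy_genome <- function(n_chrom = 2, len = 1e6, ...) {
  genome_spec(n_chrom = n_chrom, chrom_length = len, ...)
}

# Build a paint tibble for one line/chromosome from interior cut positions
# and the genotype labels of the resulting blocks.
mk_paint <- function(il, chrom, L, cuts, genos) {
  stopifnot(length(genos) == length(cuts) + 1)
  tibble::tibble(il = il, chrom = chrom,
                 start = c(1, cuts + 1), end = c(cuts, L), genotype = genos)
}

# A sites tibble that passes every filter, at the given positions.
mk_sites <- function(pos, chrom = "chr01", base_qual = 30, parent_mapq = 60,
                     depth = 10L, biallelic = TRUE) {
  n <- length(pos)
  tibble::tibble(
    chrom = chrom, pos = pos,
    allele_p1 = rep_len(c("A", "C", "G", "T"), n),
    allele_p2 = rep_len(c("C", "G", "T", "A"), n),
    base_qual = rep_len(base_qual, n),
    parent_mapq = rep_len(parent_mapq, n),
    biallelic = rep_len(biallelic, n),
    depth_p1 = rep_len(as.integer(depth), n),
    depth_p2 = rep_len(as.integer(depth), n)
  )
}

# Calls tibble for one line/chromosome.
mk_calls <- function(call, pos = seq_along(call) * 1000, il = "IL001",
                     chrom = "chr01") {
  tibble::tibble(il = il, chrom = chrom, pos = pos, call = call)
}

# Default small simulated panel shared by several tests.
sim_small_panel <- function(seed = 101, n_il = 10, n_chrom = 2, len = 5e6,
                            density = 4.9e-4) {
  g <- genome_spec(n_chrom = n_chrom, chrom_length = len, snp_density = density)
  sc <- breeding_scheme(n_il = n_il)
  sites <- simulate_parents(g, seed = seed)
  truth <- simulate_panel(g, sc, seed = seed + 1)
  list(genome = g, scheme = sc, sites = sites, truth = truth)
}
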
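---
title: "Methods: bin-map genotyping and QTL scanning for introgression-line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-map genotyping and QTL scanning for introgression-line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilbinmap)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the bundled simulator does and does not
show about real data.

## The genotyping model

An introgression line (IL) is a near-isogenic line carrying a handful of
donor chromosome segments in a recipient background, here emulating a BC₃F₇
rice panel (three backcrosses to the recipient, six generations of selfing).
Skim resequencing (~2.8× per line) cannot support per-site genotype calls,
so genotypes are assigned by a sliding-window vote over diagnostic SNPs that
distinguish the two parents:

1. **Per-SNP call** (`call_snps()`): the majority allele among a site's
   reads; ties — including zero depth — are missing. The window rule below
   consumes *calls*, not reads: with a 17-SNP window the printed 14:3 and
   5:12 thresholds sum to 17, which is what fixes this interpretation.
2. **Imputation** (`impute_calls()`, k = 5): each missing call takes the
   majority of the k nearest non-missing calls on the same chromosome by
   physical distance; a tied vote follows the single nearest neighbour. The
   paper-derived workflow names the k-nearest-neighbour family but not k;
   k = 5 is a small odd default (no ties in the usual case) and is
   configurable. Distance ties are resolved toward the leftmost neighbour so
   the procedure is deterministic.
3. **Window classification** (`classify_window()`): a 17-SNP window with
   ≥ 14 recipient calls is homozygous-recipient, ≤ 5 homozygous-donor,
   otherwise heterozygous. The asymmetry (14 vs 12 donor calls) reflects the
   direction of introgression: false donor evidence is cheaper to emit than
   false recipient evidence in a recipient-dominated genome.
4. **Blocks and breakpoints** (`paint_panel()`): windows slide in 1-SNP
   steps; runs of equal window genotype merge into blocks, and a breakpoint
   is placed at the midpoint between the central SNPs of the two windows
   flanking each transition. With 1-SNP steps, adjacent windows' centres are
   adjacent SNPs, so this attains single-SNP resolution; the source method
   says only "at the transition", and the midpoint is the symmetric,
   deterministic choice. End blocks extend to the chromosome boundaries
   because truncated windows (< 17 SNPs) would have ill-defined ratios and
   are therefore never emitted. A chromosome with fewer than 17 retained
   SNPs falls back to a single majority-call block with a warning.

### A structural property worth knowing

A sharp homozygous-to-homozygous junction drags the window count through
every intermediate ratio, so the classifier necessarily emits a band of
~8 heterozygous windows (~16 kb at the default SNP density) at such
junctions. These narrow heterozygous blocks are an artifact of the threshold
rule itself, not of this implementation; they inflate *counts* of short
heterozygous segments while leaving length-weighted genotype accuracy
essentially untouched (99.9%+ in the bundled simulations). This is one
plausible contributor to the surprisingly high heterozygous-segment counts
reported for real panels of this design. The optional `min_block_windows`
smoothing can absorb blocks spanning fewer windows than a cutoff into their
larger neighbour; it defaults to off because the reference procedure
describes no such step.

## Bin map

Breakpoints pooled over the panel partition each chromosome into candidate
bins; adjacent candidates whose genotype columns agree across every line are
merged (`build_bins()`). Merging matters because coincident or uninformative
boundaries otherwise inflate the map: the merged map is *maximal* (no two
adjacent bins agree everywhere), which the tests assert. Within a bin no
line recombines, so the bin acts as a single marker; `bin_genotypes()`
fails loudly if a paint ever changes genotype inside a bin, since that can
only be a construction bug. Gene content per bin is assigned by interval
midpoint by default — midpoints make counts additive across bins — with an
any-overlap mode available.

## Segments and coverage

Donor-derived segments are the maximal non-recipient blocks of each line,
split by zygosity so homozygous and heterozygous classes are separately
countable (`extract_segments()`). Coverage is the per-chromosome union of
all lines' segments over the chromosome length (`segment_coverage()`), with
the complement reported as gap regions. Because printed per-line length
statistics in this literature are ambiguous about whether heterozygous
segments count at full or half weight, `segment_stats()` reports both
variants.

## QTL scan

The reference analysis used an external composite-interval-mapping tool;
this package deliberately substitutes **single-marker regression on bins**
— the one methodological substitution, chosen because bins are dense, lines
carry few segments each, and a least-squares fit per bin is transparent and
exactly testable against an independent oracle. Per bin, trait and site:

\[
y = \beta_0 + \beta_1 x,\quad x \in \{-1, 0, +1\},\qquad
\mathrm{LOD} = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1},\qquad
R^2 = 1 - \frac{RSS_1}{RSS_0},
\]

with the additive effect \(\hat\beta_1\) signed so that positive means the
donor allele increases the trait. Dominance is not modelled (only additive
effects are reported in this design, where heterozygotes are rare).
Monomorphic bins are retained with missing statistics and a note; a constant
phenotype scores LOD 0 everywhere; a perfect fit reports infinite LOD rather
than a silently clamped value. The fixed LOD 2.0 threshold is carried as a
configurable constant with no further multiple-testing correction, matching
the reference analysis; under the null the per-bin exceedance rate agrees
with the \(\chi^2_1\) approximation of \(2\ln 10 \cdot \mathrm{LOD}\)
(asserted by simulation in the tests), and genome-wide null scans exceed the
threshold in a minority of replicates.

QTLs are maximal runs of contiguous significant bins; ties at the peak go to
the smaller bin id. Records from different sites merge when their supporting
runs share at least one bin — the "detected at both sites" criterion is not
spelled out in the source, and run overlap is the weakest defensible
condition. Names follow the standard rice convention (`q` + trait code +
chromosome, `.1/.2/...` suffixes in genome order), and trait-distinct QTLs
sharing a peak bin are grouped as clusters. Peak intervals extended by one
adjacent bin per side (configurable) are intersected with gene and
selective-sweep annotations on 1-based inclusive coordinates; BED input is
converted from its 0-based half-open convention on read, and the conversion
is unit-tested in both directions.

## The simulator, and what it does not show

`simulate_parents()` draws SNP positions as a renewal process with integer
gaps `min_spacing + Poisson(1/density − min_spacing)`: the expected density
is met exactly and the minimum spacing is hard, at the cost of slightly
sub-Poisson count dispersion. Defaults: 4.9 SNPs per 10 kb, 10 bp spacing,
12 × 25 Mb desk-scale genome (a `scale = "full"` flag swaps in rice-like
lengths totalling 373 Mb). Parent-site metadata (base quality ~ N(36, 5²),
parental mapping quality 60 with a 2% low-quality fraction, parental depths
~ Poisson(13.6), 0.5% non-biallelic) are chosen once so the filter stage has
realistic work to do.

`simulate_panel()` models meiosis with crossover counts per chromosome
~ Poisson(cM/100) and uniform positions — no interference, the standard
null; an obligate-crossover mode adds one guaranteed crossover per meiosis.
Each line descends from its own F₁ through backcrosses (one gamete from the
plant, one pure recipient gamete) and single-seed-descent selfings (two
independent gametes from the same plant). No marker or phenotypic selection
is modelled, although the real panels of this design were marker-selected at
BC₃F₁ — simulated segment-count distributions are therefore structurally,
not numerically, comparable to real ones. Under this model the donor-genome
fraction is 1/2⁴ ≈ 6.25% after three backcrosses and residual
heterozygosity decays by half per selfing generation; both are asserted
against Monte-Carlo simulations in the tests.

`simulate_reads()` draws depth ~ Poisson(2.83) per site and line, flips each
read's allele with probability 0.01, and leaves zero-depth sites missing; no
alignment artifacts, indels, or structural variants are modelled (alignment
is upstream of this package). `simulate_phenotypes()` is purely additive
with Gaussian residuals, and refuses causal intervals that straddle a
breakpoint in any line rather than guessing a genotype.

Passing tests on these simulations therefore demonstrate the *pipeline
logic* — filtering, painting, bin construction, statistics — under a clean
generative model; they do not certify performance under alignment bias,
segregation distortion, or selection, none of which the generator emulates.

## Problem sizes and numerical choices

The validation suite runs the panel-level checks at the study's panel size
(131 lines): parameter recovery uses 50 seeded replicates on the 12 × 25 Mb
desk genome with a single causal bin at model R² = 0.25 (peak within ±2
bins in ≥ 80% of replicates, donor-positive sign in ≥ 95%) plus a major
locus at R² = 0.9 recovered with R̂² ≥ 0.7; painting accuracy uses 131
lines on three desk chromosomes at 2.83× and 1% read error (per-bin
accuracy ≥ 97%, breakpoint recall within 200 kb ≥ 90%). Stochastic
assertions use fixed seeds and 3-standard-error bands. All coordinates are
1-based inclusive throughout; interval unions merge adjacent intervals;
regression statistics are computed from centred sums of squares and agree
with `stats::lm` to 10⁻⁹ on randomised instances.

Reproducibility is seed-exact end to end: every stochastic function takes a
seed, the pipeline derives per-stage seeds from one master seed (so a stage
can be rerun in isolation and reproduce the full run), and rerunning with
the same seed yields byte-identical outputs, recorded with checksums in the
run manifest.

## Known limitations

- No hidden-Markov or probabilistic painting alternative; the window rule is
  implemented as printed, including its heterozygous-band artifact.
- Single-marker regression, not composite interval mapping: closely linked
  QTLs on one chromosome can shadow each other, and no epistasis or
  multi-QTL model selection is attempted.
- The simulator omits selection, crossover interference beyond the obligate
  mode, and read-mapping artifacts.
- Physical coordinates only; no genetic-map (cM) estimation.
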
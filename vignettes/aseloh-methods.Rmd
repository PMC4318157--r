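---
title: "Methods: allelic imbalance, LOH detection and contaminant profiling in aseloh"
author: "aseloh authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic imbalance, LOH detection and contaminant profiling in aseloh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`aseloh` analyses bulk short-read RNA-seq of a heterozygous diploid yeast
in two fermentation conditions. Four statistical procedures form the core;
everything else is plumbing around them.

## Read matching

Reads are placed by a seed-and-extend matcher with the classical
short-read aligner contract: a read is reported only at its unique best
placement with at most `max_mismatches` (default 2) mismatches across all
reference features and offsets; reads whose best score is achieved at more
than one location are discarded as repeats. Three disjoint k-mers (k = 12
for 36-bp reads) seed the search: by pigeonhole, a placement with at most
2 mismatches leaves at least one seed exact, so the search is exact over
the contract — no heuristic losses. A brute-force scan over all offsets
serves as the oracle in the test suite. SAM from any external aligner can
be substituted via `read_sam_alignments()`.

## RPKM and the intergenic background threshold

Expression is quantified as `RPKM = 1e9 * C / (N * L)` with `C` the unique
reads on the gene, `L` its length and `N` the total reads aligned to
genes in that library. Low RPKM values are indistinguishable from
background transcription plus mismapping, so a per-library threshold is
estimated from the RPKM distribution over intergenic regions longer than
500 bp. Where the original analysis chose this threshold by visual
inspection of the gene and intergenic distributions, `aseloh` makes the
rule reproducible: the nearest-rank quantile (default 0.95) of the
intergenic RPKM values. The quantile is a tunable parameter precisely
because the published analysis does not state a numeric threshold; 0.95
keeps the family-wise background contamination of the expressed set low
without discarding weakly expressed genes wholesale. A gene enters a
pairwise differential-expression comparison if it clears the threshold in
at least one of the two libraries; the published rule only discards genes
below threshold "in the respective libraries", i.e. in both.

## Differential expression

The published analysis reports thresholds (expression ratio at least
2-fold, p < 0.01) but not the exact statistic of the tool it used, so the
two-library test is specified here as the standard exact conditional
construction for a rate ratio: conditional on `C1 + C2`, `C1 ~
Binomial(C1 + C2, N1/(N1+N2))` under the null of equal per-read rates; the
two-sided p-value uses the minimum-likelihood method, and a pseudocount of
1 replaces zero counts in the fold change only. This choice is exact at
any depth, has no tuning parameters, and is verified against full outcome
enumeration in the tests. For grouped comparisons (time points as
replicates) the test is a Welch two-sample test on `log2(RPKM + 1)` with
fold change on group mean RPKM. No multiple-testing correction is applied
by default, matching the published raw `p < 0.01` rule; BH correction is
available behind a flag. Because the exact test is conservative, the
type-I fraction on null simulations stays at or below the nominal level.

## Differential allelic expression

For genes with phased heterozygous SNPs, each aligned read overlapping at
least one SNP votes for haplotype 1 or 2 by comparing its bases at the
overlapped SNP positions; mixed or impossible votes make the read
`conflicting` and it is excluded from informative depth (no fractional
splitting). Imbalance is cumulative across the whole gene — a read is
counted once however many SNPs it covers. A gene is called DAE for an
allele when:

- informative depth `reads_h1 + reads_h2 >= min_depth` (default 20), and
- that allele holds at least `min_ratio/(min_ratio+1)` of informative
  reads (default 2-fold, i.e. 2/3).

The depth floor is a design choice: the published rule states no floor,
but at depth below ~20 a 2-fold ratio is indistinguishable from sampling
noise. The boundary is inclusive: exactly 2:1 qualifies, reading the
published "more than 66%" as the prose gloss of the 2-fold rule
(2/3 = 66.7% > 66%). DAE is called per condition by pooling the
condition's libraries, since published DAE sets are reported per
fermentation condition rather than per time point.

## LOH run detection

A mitotic-recombination LOH event shows as a run of consecutive genes
that are essentially monoallelic with the same dominant haplotype. The
detector scans each chromosome's genes in coordinate order and reports
maximal runs of genes with major-allele fraction at least `mono_fraction`
(default 0.95, operationalising "essentially one allele"), bridging up to
`max_uninformative_gap` (default 2) consecutive uninformative genes —
SNP-free or low-depth genes cannot interrupt a block, mirroring the
homozygous stretches where no allelic information exists. Runs with fewer
than `min_genes` (default 10) monoallelic genes are discarded, and the
span is measured from the first to the last monoallelic gene (gene-start
to gene-end; a SNP-based convention would differ by less than one gene
length). An exhaustive window-enumeration oracle checks the detector on
short chromosomes in the tests. Before comparing DAE between conditions,
the arm carrying the longest detected run is excluded
(`exclude_region()` from the run's start position), separating the
structural event from regulatory imbalance.

## rRNA taxonomy

Reads that fail gene/intergenic alignment are classified against a
lineage-labelled rRNA reference (SILVA-style headers). A unique best hit
inherits the fragment's full seven-rank lineage. For tied hits the
published pipeline discarded repeats outright; `aseloh` keeps a tie when
the tied lineages agree below domain, truncating to their lowest common
ancestor, and discards it otherwise. This preserves strictly more
information while never inventing resolution; `strict = TRUE` restores
pure discarding. Families below 5% of classified bacterial reads are
dropped (boundary retained); within-family species fractions are computed
over the family's classified reads.

# The synthetic-data generator

The generator is first-class, tested code: it emulates exactly the
structure the analysis assumes, so recovery is a meaningful test of the
analysis rather than of the simulator.

What it emulates: a diploid transcriptome as per-gene haplotype pairs
differing exactly at phased SNP positions; genes laid on chromosomes with
intergenic gaps all > 500 bp (every gap qualifies for the background set);
a planted contiguous monoallelic block (LOH) at a chromosome end with a
calibrated genomic span; planted gene sets with 3:1 allelic imbalance in
one or both conditions; uniform low-level intergenic background reads;
and an rRNA admixture with exact per-species read counts
(largest-remainder allocation, not multinomial sampling, so planted
community fractions are hit exactly). Reads are error-free, 36 bp,
single-end, fixed quality.

What it does not emulate — and hence what passing tests do not show about
real data: sequencing error and quality variation, coverage bias (GC,
position, fragmentation), introns and overlapping genes, mapping bias
toward the reference haplotype, unphased or mis-phased SNPs, and
polyA-selection effects on rRNA content. On real libraries the DAE
boundary behaviour and the aligner's repeat handling therefore need the
conservative depth floor much more than the simulations do.

Design choices worth recording:

- *SNP spacing.* SNPs within a gene are at least 20 bp apart, so a 36-bp
  read spans at most two SNPs and reads from either haplotype always fit
  the 2-mismatch budget against the haplotype-1 reference; no
  allele-dependent alignment loss can distort allelic fractions.
- *Coverage model.* Presets that exist for parameter recovery set a
  per-gene informative-depth target (the number of SNP-overlapping
  reads); per-gene totals are derived from each gene's exact informative
  start fraction and the library size follows. Alternatively a fixed
  `reads_per_library` is distributed over genes by log-normal expression
  weights.
- *Powering the allelic preset.* The full-scale allelic preset uses an
  informative-depth target of 500 reads per gene. At that depth a planted
  3:1 gene lies more than 4 binomial standard deviations above the 2/3
  calling boundary and a balanced gene more than 7 below it, so the
  probability that any of the ~1,500 genes flips its call anywhere in a
  run is below about one percent — planted counts are recovered exactly,
  as the acceptance checks require, with no seed hunting.
- *Span calibration.* The planted block's intergenic gaps are drawn
  uniformly within ±15% of the mean gap implied by the target span, so
  the realised span concentrates within ~1% of the target.
- *Determinism.* One RNG stream per artefact: the reference is generated
  under the configuration seed; each library under a seed derived from
  (seed, condition). Identical configurations give byte-identical FASTQ
  and truth tables; conditions are independent but reproducible.

# Numerical and degenerate-input conventions

Coordinates are 1-based inclusive throughout (GFF3/VCF convention).
Zero-count genes have RPKM 0 by definition; `N = 0` or `L = 0` signal
errors rather than returning NaN. The background quantile uses the
nearest-rank rule (type-1 empirical quantile), so thresholds are always
attained values and monotone in the quantile. In DAE calling an exactly
balanced gene is `balanced`, the allelic ratio is infinite when one
haplotype has zero reads, and ties at the 2-fold boundary are called. The
LOH detector requires runs to start and end on a monoallelic gene
(flanking uninformative genes are trimmed); segments on a chromosome are
disjoint and maximal by construction. The restriction digest cuts before
every site occurrence; a site at position 1 yields no 5' fragment, and
fragment lengths always sum to the input length.

# Problem sizes

The bundled presets are sized for a desk run: the smoke preset (50 genes)
exercises every stage in seconds; the full allelic preset (~1,500 genes,
two libraries of ~3.4 million 36-bp reads) completes in well under five
minutes on one CPU; the mock-community presets (20,000 reads each) in
seconds. These sizes are the package's own choices for routine
verification; all knobs scale up through `sim_config()`.

# Known limitations

The matcher is exact only for the ≤2-mismatch unique-best contract (no
indels, no quality awareness). The DE tests model no overdispersion
between biological replicates — the exact binomial treats the two
libraries as sequencing draws, which is anticonservative for biological
variability; the grouped Welch test is the appropriate tool when
replicates exist. DAE calling ignores reference-mapping bias (harmless on
error-free synthetic data; real data may need WASP-style remapping).
Lineage handling assumes the fixed seven-rank SILVA-style taxonomy
string.
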
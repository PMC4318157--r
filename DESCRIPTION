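Package: aseloh
Title: Allele-Specific Expression, Loss-of-Heterozygosity Detection and
    Contaminant Profiling for Industrial Yeast RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested re-implementation of the bespoke
    computational analyses used in industrial-scale fed-batch yeast
    fermentation RNA-seq studies: haplotype-resolved read counting over
    phased heterozygous SNPs and differential allelic expression (DAE)
    calling at a 2-fold threshold, run-detection of contiguous monoallelic
    gene blocks diagnostic of loss of heterozygosity (LOH), RPKM
    quantification with an intergenic-background expression threshold,
    fold-change/p-value differential expression on two-library count data,
    and taxonomic profiling of residual bacterial rRNA reads against a
    lineage-labelled reference. Ships a deterministic synthetic-data
    generator (references, phased VCF, 36-bp single-end reads, truth
    tables) with named presets mirroring published allelic architectures
    and mock bacterial communities, a built-in unique-best short-read
    matcher (up to two mismatches), an in-silico restriction digest
    utility, and an end-to-end pipeline driver with TSV outputs and a
    summary report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
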
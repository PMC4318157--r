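# Synthetic-data generator: determinism, conservation, planted structure.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(intergenic_background_rate = 1.2), "in \\[0,1\\]")
  expect_error(sim_config(rrna_mix = c(a = 0.6), intergenic_background_rate = 0.5),
               "sum to <= 1")
  expect_error(sim_config(gene_length_bp = c(100, 200), read_length_bp = 150),
               "read_length")
  expect_error(sim_config(gene_length_bp = c(100, 200), snps_per_gene = c(0, 50)),
               "SNP count")
  expect_error(sim_preset("nope"), "arg")
  # planted DAE sets larger than the genes available off the LOH chromosome
  expect_error(sim_config(n_chromosomes = 2, genes_per_chromosome = 5,
                          planted_loh = list(chromosome = 2, n_genes = 5,
                                             span_bp = 30000),
                          planted_dae = list(both = 4, a_only = 2,
                                             b_only = 0, ratio = 3)),
               "disjoint")
})

test_that("reference bundle is deterministic and respects its contracts", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 8,
                    gene_length_bp = c(300, 500), read_length_bp = 30,
                    snps_per_gene = c(0, 4), informative_depth = 50,
                    seed = 7)
  ref1 <- build_reference(cfg)
  ref2 <- build_reference(cfg)
  expect_identical(ref1$seq_h1, ref2$seq_h1)
  expect_identical(ref1$genes, ref2$genes)

  # haplotypes differ exactly at SNP positions
  for (g in ref1$genes$gene_id) {
    s <- ref1$snps[ref1$snps$gene_id == g, ]
    d <- which(strsplit(ref1$seq_h1[[g]], "")[[1]] !=
                 strsplit(ref1$seq_h2[[g]], "")[[1]])
    expect_identical(d, as.integer(s$local_pos))
  }

  # every intergenic region exceeds 500 bp
  expect_true(all(ref1$intergenic$length > 500))

  # byte-identical bundles on disk for the same seed
  d1 <- tempfile(); d2 <- tempfile()
  write_reference_bundle(ref1, d1)
  write_reference_bundle(ref2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a zero-SNP configuration yields an empty VCF", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 5,
                    gene_length_bp = c(200, 300), read_length_bp = 36,
                    snps_per_gene = c(0, 0), informative_depth = 10, seed = 3)
  ref <- build_reference(cfg)
  expect_identical(nrow(ref$snps), 0L)
  d <- tempfile(); write_reference_bundle(ref, d)
  vcf_lines <- readLines(file.path(d, "snps.vcf"))
  expect_true(all(startsWith(vcf_lines, "#")))
  unlink(d, recursive = TRUE)
})

test_that("library simulation conserves reads and hits planted allocations", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 10,
                    gene_length_bp = c(300, 500), read_length_bp = 30,
                    snps_per_gene = c(1, 3), informative_depth = NULL,
                    reads_per_library = 5000L,
                    intergenic_background_rate = 0.04,
                    rrna_mix = c("Bacteria;F;C;O;Fam1;G;Sp1" = 0.10,
                                 "Bacteria;F;C;O;Fam2;G;Sp2" = 0.03),
                    seed = 11)
  ref <- build_reference(cfg)
  lib <- simulate_library(ref, "A")
  # conservation: read count equals the configured library size, and the
  # truth table has exactly one row per read
  expect_identical(lib$n_reads, 5000L)
  expect_identical(nrow(lib$truth), 5000L)
  expect_identical(anyDuplicated(lib$truth$read_id), 0L)
  # exact admixture allocation: round(f * n) reads per rRNA species
  tab <- table(lib$truth$lineage)
  expect_identical(as.integer(tab[["Bacteria;F;C;O;Fam1;G;Sp1"]]), 500L)
  expect_identical(as.integer(tab[["Bacteria;F;C;O;Fam2;G;Sp2"]]), 150L)
  expect_identical(sum(lib$truth$source == "intergenic"), 200L)

  # determinism: identical FASTQ bytes for the same (config, condition)
  lib2 <- simulate_library(ref, "A")
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(lib, f1); write_fastq(lib2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # conditions get independent but reproducible streams
  libB <- simulate_library(ref, "B")
  expect_false(identical(lib$reads, libB$reads))
  unlink(c(f1, f2))
})

test_that("zero background rate puts no read on an intergenic region", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 6,
                    gene_length_bp = c(300, 400), read_length_bp = 30,
                    snps_per_gene = c(1, 2), informative_depth = 40,
                    intergenic_background_rate = 0,
                    rrna_mix = c("Bacteria;F;C;O;Fam1;G;Sp1" = 0.02),
                    seed = 5)
  ref <- build_reference(cfg)
  lib <- simulate_library(ref, "A")
  expect_identical(sum(lib$truth$source == "intergenic"), 0L)
})

test_that("reads of an LOH gene all carry the dominant haplotype", {
  cfg <- sim_preset("smoke")
  ref <- build_reference(cfg)
  loh_genes <- ref$genes$gene_id[ref$genes$role == "loh"]
  expect_length(loh_genes, 12)
  lib <- simulate_library(ref, "A")
  hap <- lib$truth$haplotype[lib$truth$feature %in% loh_genes]
  expect_true(all(hap == 1L))
})

test_that("unknown condition labels are rejected", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 4,
                    gene_length_bp = c(200, 300), read_length_bp = 36,
                    snps_per_gene = c(0, 1), informative_depth = 10, seed = 2)
  ref <- build_reference(cfg)
  expect_error(simulate_library(ref, "nope"), "unknown condition")
})

test_that("planted 3:1 genes sit far from the 2-fold boundary at preset coverage", {
  # recovery margin, assertable analytically from the configuration: the
  # distance between the planted major-allele fraction and the calling
  # boundary exceeds 10 binomial SD at the configured informative depth
  cfg <- sim_preset("paper_fig5")
  ratio <- cfg$planted_dae$ratio
  p <- ratio / (ratio + 1)
  depth <- cfg$informative_depth
  sd <- sqrt(p * (1 - p) / depth)
  expect_gt((p - 0.5) / sd, 10) # planted 3:1 vs balanced null
})

test_that("presets encode the published compositions", {
  fig5 <- sim_preset("paper_fig5")
  expect_identical(fig5$planted_loh$n_genes, 140)
  expect_identical(fig5$planted_loh$span_bp, 600000)
  expect_identical(fig5$planted_dae[c("both", "a_only", "b_only")],
                   list(both = 55, a_only = 61, b_only = 33))
  for (nm in c("paper_fig1b_fl", "paper_fig1b_tf")) {
    cfg <- sim_preset(nm)
    mix <- cfg$rrna_mix
    fam <- vapply(strsplit(names(mix), ";"), `[`, "", 5)
    lacto <- sum(mix[fam == "Lactobacillaceae"])
    ferm <- mix[grepl("fermentum", names(mix))]
    expect_equal(unname(ferm / lacto),
                 if (nm == "paper_fig1b_fl") 0.93 else 0.41)
    # at least two other families, each >= 5% of bacterial reads
    other <- tapply(mix, fam, sum)
    other <- other[names(other) != "Lactobacillaceae"]
    expect_gte(length(other), 2)
    expect_true(all(other / sum(mix) >= 0.05))
  }
})
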
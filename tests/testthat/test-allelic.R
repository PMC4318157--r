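# Haplotype assignment, cumulative allele counting, DAE calling, LOH runs,
# region exclusion and the condition Venn.

test_that("single-read haplotype assignment is unanimous or conflicting", {
  g <- toy_gene()
  # read covering one SNP with the h1 base
  expect_identical(assign_read_haplotype(substr(g$seq_h1, 1, 20), 1, g$snps),
                   "h1")
  # read covering both SNPs with h2 bases
  h2seq <- subst_h <- g$seq_h1
  substr(h2seq, 11, 11) <- "T"; substr(h2seq, 41, 41) <- "A"
  expect_identical(assign_read_haplotype(substr(h2seq, 5, 45), 5, g$snps),
                   "h2")
  # mixed support across the two SNPs
  mix <- g$seq_h1; substr(mix, 41, 41) <- "A"
  expect_identical(assign_read_haplotype(substr(mix, 5, 45), 5, g$snps),
                   "conflicting")
  # a base matching neither haplotype
  bad <- g$seq_h1; substr(bad, 11, 11) <- "G"
  expect_identical(assign_read_haplotype(substr(bad, 1, 20), 1, g$snps),
                   "conflicting")
  # no SNP overlapped
  expect_identical(assign_read_haplotype(substr(g$seq_h1, 42, 60), 42, g$snps),
                   "uninformative")
})

test_that("allele counts are cumulative per gene, one count per read", {
  asg <- data.frame(
    read_id = sprintf("r%02d", 1:45),
    gene_id = "g1",
    assignment = c(rep("h1", 30), rep("h2", 15)),
    stringsAsFactors = FALSE)
  rec <- accumulate_gene_alleles(asg, "A")
  expect_identical(rec$reads_h1, 30L)
  expect_identical(rec$reads_h2, 15L)
  expect_identical(rec$reads_conflicting, 0L)
  # empty input with a declared universe
  rec0 <- accumulate_gene_alleles(asg[0, ], "A", gene_ids = c("g1", "g2"))
  expect_identical(rec0$reads_h1, c(0L, 0L))
  # batch path counts a double-SNP-spanning read once
  g <- toy_gene()
  reads <- c(rA = substr(g$seq_h1, 5, 45)) # spans both SNPs
  al <- data.frame(read_id = "rA", feature = "g1", pos = 5L, mismatches = 0L,
                   status = "unique", stringsAsFactors = FALSE)
  batch <- aseloh:::assign_read_haplotypes(al, reads, g$snps)
  expect_identical(nrow(batch), 1L)
  expect_identical(batch$assignment, "h1")
})

test_that("DAE calls respect the 2-fold boundary and depth floor", {
  rec <- data.frame(gene_id = sprintf("g%d", 1:5), condition = "A",
                    reads_h1 = c(67, 66, 50, 10, 40),
                    reads_h2 = c(33, 34, 50, 0, 20),
                    reads_conflicting = 0L, stringsAsFactors = FALSE)
  calls <- call_dae(rec, min_depth = 20)
  # 67:33 -> ratio ~2.03, fraction 67%: called
  expect_identical(calls$call[1], "allele1")
  # 66:34 -> ratio ~1.94: balanced
  expect_identical(calls$call[2], "balanced")
  # 50:50: balanced
  expect_identical(calls$call[3], "balanced")
  # depth 10 < 20: uninformative even though fully monoallelic
  expect_identical(calls$call[4], "uninformative")
  # exactly 2:1 (the boundary) qualifies
  expect_identical(calls$call[5], "allele1")
  expect_identical(calls$allelic_ratio[4], Inf)
  # the boundary fraction is 2/3, i.e. 66% truncated to whole percent
  expect_identical(floor(100 * dae_min_fraction(2)), 66)
})

test_that("allele symmetry: swapping haplotype labels swaps calls", {
  set.seed(14)
  rec <- data.frame(gene_id = sprintf("g%02d", 1:50), condition = "A",
                    reads_h1 = rpois(50, 40), reads_h2 = rpois(50, 40),
                    reads_conflicting = rpois(50, 2),
                    stringsAsFactors = FALSE)
  a <- call_dae(rec)
  swapped <- transform(rec, reads_h1 = rec$reads_h2, reads_h2 = rec$reads_h1)
  b <- call_dae(swapped)
  map <- c(allele1 = "allele2", allele2 = "allele1", balanced = "balanced",
           uninformative = "uninformative")
  expect_identical(unname(map[a$call]), b$call)
  # informative fractions are complementary
  inf <- a$call != "uninformative"
  expect_equal(a$allele1_fraction[inf] + b$allele1_fraction[inf],
               rep(1, sum(inf)))
})

test_that("LOH run detection handles gaps, flanks and minimum size", {
  mk <- function(states) {
    n <- length(states)
    starts <- seq(1L, by = 2000L, length.out = n)
    af <- ifelse(states == "1", 1, ifelse(states == "2", 0,
                                          ifelse(states == "b", 0.5, NA)))
    data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chrX",
               start = starts, end = starts + 999L,
               allele1_fraction = af,
               call = ifelse(states == "u", "uninformative",
                             ifelse(states == "b", "balanced",
                                    ifelse(states == "1", "allele1",
                                           "allele2"))),
               stringsAsFactors = FALSE)
  }
  # alternating calls: no run
  segs <- detect_loh_runs(mk(rep(c("1", "2"), 10)), min_genes = 3)
  expect_identical(nrow(segs), 0L)
  # a 20-gene monoallelic run interrupted by one uninformative gene:
  # one segment of 20 informative genes spanning the gap
  states <- c("b", rep("1", 10), "u", rep("1", 10), "b")
  segs <- detect_loh_runs(mk(states), min_genes = 10)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$gene_count, 20L)
  expect_identical(segs$dominant_haplotype, 1L)
  # span runs from the first to the last monoallelic gene
  calls <- mk(states)
  expect_identical(segs$start, calls$start[2])
  expect_identical(segs$end, calls$end[22])
  # three consecutive uninformative genes break the run at the default gap
  states3 <- c(rep("1", 10), "u", "u", "u", rep("1", 10))
  segs3 <- detect_loh_runs(mk(states3), min_genes = 5)
  expect_identical(nrow(segs3), 2L)
  # runs below min_genes are dropped; removing and re-adding the filter is
  # idempotent
  segs_all <- detect_loh_runs(mk(states3), min_genes = 1)
  expect_identical(segs_all[segs_all$gene_count >= 5, ]$gene_count,
                   segs3$gene_count)
  # flanking uninformative genes are trimmed, not absorbed
  states4 <- c("u", rep("1", 8), "u")
  segs4 <- detect_loh_runs(mk(states4), min_genes = 5)
  expect_identical(segs4$start, mk(states4)$start[2])
  expect_identical(segs4$end, mk(states4)$end[9])
  expect_error(detect_loh_runs(mk(c("1", "1"))[2:1, ]), "sorted")
})

test_that("LOH detector agrees with exhaustive window enumeration", {
  set.seed(77)
  for (rep_i in 1:12) {
    n <- sample(10:40, 1)
    states <- sample(c("1", "2", "b", "u"), n, replace = TRUE,
                     prob = c(0.4, 0.2, 0.2, 0.2))
    starts <- cumsum(sample(1000:3000, n))
    af <- ifelse(states == "1", runif(n, 0.97, 1),
                 ifelse(states == "2", runif(n, 0, 0.03),
                        ifelse(states == "b", runif(n, 0.4, 0.6), NA)))
    calls <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chrZ",
                        start = starts, end = starts + 800L,
                        allele1_fraction = af,
                        call = ifelse(states == "u", "uninformative",
                                      ifelse(states == "b", "balanced",
                                             ifelse(states == "1", "allele1",
                                                    "allele2"))),
                        stringsAsFactors = FALSE)
    for (min_genes in c(1, 3)) for (gap in c(0, 2)) {
      got <- detect_loh_runs(calls, min_genes = min_genes,
                             max_uninformative_gap = gap)
      want <- brute_loh(calls, min_genes = min_genes, max_gap = gap)
      expect_identical(got$start, as.integer(want$start))
      expect_identical(got$end, as.integer(want$end))
      expect_identical(got$gene_count, as.integer(want$gene_count))
      expect_identical(got$dominant_haplotype,
                       as.integer(want$dominant_haplotype))
      # segments never overlap
      if (nrow(got) > 1)
        expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    }
  }
})

test_that("region exclusion trims by chromosome and position", {
  calls <- random_calls(30, seed = 5)
  expect_identical(nrow(exclude_region(calls, "chrT", max(calls$start) + 1)),
                   30L)
  expect_identical(nrow(exclude_region(calls, "chrT", 1)), 0L)
  cut <- calls$start[20]
  kept <- exclude_region(calls, "chrT", cut)
  expect_identical(nrow(kept), 19L)
  expect_true(all(kept$start < cut))
  # other chromosomes untouched
  expect_identical(nrow(exclude_region(calls, "chrOther", 1)), 30L)
})

test_that("condition comparison partitions DAE genes disjointly", {
  a <- random_calls(40, seed = 6)
  b <- random_calls(40, seed = 60)
  v <- compare_conditions(a, b)
  expect_length(intersect(v$both, v$a_only), 0)
  expect_length(intersect(v$both, v$b_only), 0)
  expect_length(intersect(v$a_only, v$b_only), 0)
  dae_a <- a$gene_id[a$call %in% c("allele1", "allele2")]
  dae_b <- b$gene_id[b$call %in% c("allele1", "allele2")]
  expect_setequal(c(v$both, v$a_only, v$b_only), union(dae_a, dae_b))
  # identical conditions: nothing exclusive
  v2 <- compare_conditions(a, a)
  expect_length(v2$a_only, 0)
  expect_length(v2$b_only, 0)
  expect_setequal(v2$both, dae_a)
  expect_error(compare_conditions(a, b[1:10, ]), "universe")
})
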
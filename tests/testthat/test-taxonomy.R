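# rRNA classification, rank aggregation, the 5% family cutoff and
# within-family species fractions.

make_ref <- function() {
  set.seed(55)
  lin <- c(
    ferm = "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus_fermentum",
    delb = "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus_delbrueckii",
    acet = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodospirillales;Acetobacteraceae;Acetobacter;Acetobacter_pasteurianus")
  data.frame(frag_id = names(lin), lineage = unname(lin),
             seq = replicate(3, paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                                      collapse = "")),
             stringsAsFactors = FALSE)
}

test_that("reads inherit the lineage of their unique best hit", {
  ref <- make_ref()
  reads <- c(a = substr(ref$seq[1], 10, 45),
             b = substr(ref$seq[3], 50, 85),
             c = strrep("ACGTACGTA", 4)) # matches nothing within 2 mismatches
  cls <- classify_reads(reads, ref)
  expect_identical(cls$assigned, c(TRUE, TRUE, FALSE))
  expect_identical(cls$lineage[1], ref$lineage[1])
  expect_identical(cls$lineage[2], ref$lineage[3])
})

test_that("tied hits are salvaged at the lowest common ancestor", {
  ref <- make_ref()
  shared <- substr(ref$seq[1], 1, 36)
  # plant the same 36-mer into the sister species' fragment
  ref2 <- ref
  ref2$seq[2] <- paste0(shared, substr(ref$seq[2], 37, 200))
  cls <- classify_reads(c(r = shared), ref2)
  # agreement down to genus, truncated before species
  expect_true(cls$assigned)
  expect_identical(
    cls$lineage,
    "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus")
  # strict mode reproduces pure repeat-discarding
  cls_strict <- classify_reads(c(r = shared), ref2, strict = TRUE)
  expect_false(cls_strict$assigned)
  # ties meeting only at domain stay discarded
  ref3 <- ref
  ref3$seq[3] <- paste0(shared, substr(ref$seq[3], 37, 200))
  cls3 <- classify_reads(c(r = shared), ref3)
  expect_false(cls3$assigned)
})

test_that("per-rank tallies conserve reads and nest correctly", {
  lins <- c(rep("Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus_fermentum", 7),
            rep("Bacteria;Proteobacteria;Alphaproteobacteria;Rhodospirillales;Acetobacteraceae;Acetobacter;Acetobacter_pasteurianus", 3),
            "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae", # unresolved below family
            NA) # unassigned
  fam <- counts_per_taxon(lins, "family")
  expect_identical(fam$count[fam$taxon == "Lactobacillaceae"], 8L)
  expect_identical(fam$count[fam$taxon == "Acetobacteraceae"], 3L)
  expect_identical(sum(fam$count), 11L) # assigned reads only
  expect_equal(sum(fam$fraction), 1)
  gen <- counts_per_taxon(lins, "genus")
  expect_identical(gen$count[gen$taxon == "unresolved"], 1L)
  # family counts >= sum of nested genus counts
  expect_gte(fam$count[fam$taxon == "Lactobacillaceae"],
             sum(gen$count[gen$taxon == "Lactobacillus"]))
  # empty input
  expect_identical(nrow(counts_per_taxon(character(0), "family")), 0L)
  # 7 vs 3 fully resolved reads: fractions 0.7 / 0.3 of those reads
  fam2 <- counts_per_taxon(lins[1:10], "family")
  expect_equal(fam2$fraction, c(0.7, 0.3))
})

test_that("family cutoff removes <5% and keeps the boundary", {
  fam <- data.frame(taxon = c("A", "B", "C", "unresolved"),
                    rank = "family", lineage = c("d;p;c;o;A", "d;p;c;o;B",
                                                 "d;p;c;o;C", "unresolved"),
                    count = c(910L, 50L, 40L, 0L),
                    fraction = c(0.91, 0.05, 0.04, 0),
                    stringsAsFactors = FALSE)
  kept <- apply_family_cutoff(fam, 0.05)
  expect_setequal(kept$taxon, c("A", "B")) # 4% removed, exactly 5% retained
  # a single family at 100% is retained
  one <- fam[1, ]; one$fraction <- 1
  expect_identical(apply_family_cutoff(one)$taxon, "A")
})

test_that("species fractions divide by their family total", {
  lins <- c(rep("d;p;c;o;FamA;G;sp1", 9), rep("d;p;c;o;FamA;G;sp2", 1),
            rep("d;p;c;o;FamB;H;sp3", 5))
  spc <- counts_per_taxon(lins, "species")
  expect_equal(species_fraction(spc, "FamA", "sp1"), 0.9)
  expect_equal(species_fraction(spc, "FamB", "sp3"), 1)
  expect_error(species_fraction(spc, "FamC", "sp1"), "no classified reads")
})

test_that("simulated mock communities are recovered exactly", {
  # error-free reads from unique references: planted rank fractions are
  # reproduced without error, and assigned + unassigned = total
  cfg <- sim_preset("paper_fig1b_fl")
  ref <- build_reference(cfg)
  lib <- simulate_library(ref, cfg$conditions[1])
  rrna_truth <- !is.na(lib$truth$lineage)
  cls <- classify_reads(lib$reads[rrna_truth], ref$rrna)
  expect_identical(nrow(cls), sum(rrna_truth))
  expect_true(all(cls$assigned))
  fam <- counts_per_taxon(cls, "family")
  truth_fam <- vapply(strsplit(lib$truth$lineage[rrna_truth], ";"), `[`, "", 5)
  want <- table(truth_fam)
  expect_identical(setNames(fam$count, fam$taxon)[sort(names(want))],
                   setNames(as.integer(want), names(want))[sort(names(want))])
})
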
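## Synthetic-data generator: reference bundles, phased SNPs, 36-bp single-end
## reads and per-read truth tables, with named presets that mirror published
## allelic architectures and mock bacterial communities.

#' Build a simulation configuration
#'
#' Collects every generative knob of the synthetic RNA-seq model: a
#' heterozygous diploid transcriptome with a planted contiguous monoallelic
#' (LOH) gene block, gene sets with condition-specific allelic imbalance,
#' low-level intergenic background transcription, and a bacterial rRNA read
#' admixture with a fixed lineage composition.
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome integer scalar or vector (length
#'   `n_chromosomes`) of gene counts per chromosome.
#' @param gene_length_bp length-2 range (bp) genes are sampled from.
#' @param snps_per_gene length-2 range of phased heterozygous SNP counts per
#'   gene; SNPs are placed at least `min_snp_spacing` bp apart so a single
#'   read never spans more than `floor(read_length_bp / min_snp_spacing)` of
#'   them.
#' @param read_length_bp single-end read length (default 36 bp).
#' @param reads_per_library total reads per simulated library, or `NA` to
#'   derive the library size from `informative_depth` (see Details).
#' @param informative_depth if non-`NULL`, target number of SNP-overlapping
#'   (haplotype-informative) reads per gene; per-gene read counts are then
#'   `ceiling(informative_depth / p_g)` where `p_g` is the gene's exact
#'   fraction of read start positions that overlap at least one SNP.
#' @param conditions character vector of condition labels (two by default).
#' @param planted_loh `NULL`, or `list(chromosome=, n_genes=, span_bp=,
#'   haplotype=)`: the last `n_genes` genes of that chromosome form one
#'   contiguous fully monoallelic block whose genomic span (first gene start
#'   to last gene end) is calibrated to `span_bp`.
#' @param planted_dae `list(both=, a_only=, b_only=, ratio=)`: numbers of
#'   genes with allelic imbalance in both conditions, in the first condition
#'   only, and in the second only, at major:minor ratio `ratio` (default 3).
#'   Sets are disjoint and drawn off the LOH chromosome.
#' @param intergenic_gap_bp length-2 range for intergenic gaps (all > 500 bp
#'   so every region qualifies for the background set).
#' @param intergenic_background_rate fraction of reads drawn from intergenic
#'   regions.
#' @param rrna_mix named numeric vector mapping full semicolon-delimited
#'   lineage strings (domain;phylum;class;order;family;genus;species) to the
#'   fraction of total reads drawn from that species' rRNA fragments.
#' @param min_snp_spacing minimum distance between SNPs of one gene (bp).
#' @param seed integer master seed; every downstream stream is derived from
#'   it.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [sim_preset()], [build_reference()], [simulate_library()]
#' @export
sim_config <- function(n_chromosomes = 2,
                       genes_per_chromosome = 25,
                       gene_length_bp = c(500, 1500),
                       snps_per_gene = c(0, 8),
                       read_length_bp = 36,
                       reads_per_library = NA_integer_,
                       informative_depth = 100,
                       conditions = c("A", "B"),
                       planted_loh = NULL,
                       planted_dae = list(both = 0, a_only = 0, b_only = 0,
                                          ratio = 3),
                       intergenic_gap_bp = c(501, 1500),
                       intergenic_background_rate = 0.02,
                       rrna_mix = c(
                         "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus_fermentum" = 0.005),
                       min_snp_spacing = 20,
                       seed = 101) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              gene_length_bp = as.integer(gene_length_bp),
              snps_per_gene = as.integer(snps_per_gene),
              read_length_bp = as.integer(read_length_bp),
              reads_per_library = as.integer(reads_per_library),
              informative_depth = informative_depth,
              conditions = conditions,
              planted_loh = planted_loh,
              planted_dae = planted_dae,
              intergenic_gap_bp = as.integer(intergenic_gap_bp),
              intergenic_background_rate = intergenic_background_rate,
              rrna_mix = rrna_mix,
              min_snp_spacing = as.integer(min_snp_spacing),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1,
            length(cfg$gene_length_bp) == 2,
            cfg$gene_length_bp[1] <= cfg$gene_length_bp[2],
            length(cfg$snps_per_gene) == 2,
            cfg$snps_per_gene[1] >= 0)
  if (!length(cfg$genes_per_chromosome) %in% c(1L, cfg$n_chromosomes))
    stop("genes_per_chromosome must be scalar or one value per chromosome")
  if (cfg$read_length_bp > cfg$gene_length_bp[1])
    stop("read_length_bp must not exceed the minimum gene length")
  rate <- cfg$intergenic_background_rate
  if (rate < 0 || rate > 1) stop("intergenic_background_rate must be in [0,1]")
  if (any(cfg$rrna_mix < 0) || any(cfg$rrna_mix > 1))
    stop("rrna_mix fractions must be in [0,1]")
  if (sum(cfg$rrna_mix) + rate > 1)
    stop("rrna_mix fractions plus background rate must sum to <= 1")
  ## SNPs at min spacing must fit in the shortest gene
  need <- (cfg$snps_per_gene[2] - 1) * cfg$min_snp_spacing + 1
  if (cfg$snps_per_gene[2] > 0 && need > cfg$gene_length_bp[1])
    stop("maximum SNP count does not fit the minimum gene length at the ",
         "configured spacing")
  dae <- cfg$planted_dae
  if (!all(c("both", "a_only", "b_only") %in% names(dae)))
    stop("planted_dae needs fields both, a_only, b_only")
  if (is.null(dae$ratio)) dae$ratio <- 3
  if (dae$ratio <= 1) stop("planted_dae ratio must exceed 1")
  if (length(cfg$conditions) < 2) stop("need at least two condition labels")
  loh <- cfg$planted_loh
  if (!is.null(loh)) {
    stopifnot(all(c("chromosome", "n_genes", "span_bp") %in% names(loh)))
    gpc <- rep_len(cfg$genes_per_chromosome, cfg$n_chromosomes)
    if (loh$chromosome > cfg$n_chromosomes)
      stop("planted_loh chromosome out of range")
    if (loh$n_genes > gpc[loh$chromosome])
      stop("planted_loh block larger than its chromosome")
    n_avail <- sum(gpc) - gpc[loh$chromosome]
    if (dae$both + dae$a_only + dae$b_only > n_avail)
      stop("planted DAE gene sets exceed the genes available off the LOH ",
           "chromosome (sets must be disjoint)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  gpc <- rep_len(x$genes_per_chromosome, x$n_chromosomes)
  cat("Synthetic RNA-seq configuration\n")
  cat(sprintf("  %d chromosomes, %d genes, read length %d bp, seed %d\n",
              x$n_chromosomes, sum(gpc), x$read_length_bp, x$seed))
  if (!is.null(x$planted_loh))
    cat(sprintf("  planted LOH: chr%d, %d genes, ~%d bp\n",
                x$planted_loh$chromosome, x$planted_loh$n_genes,
                x$planted_loh$span_bp))
  cat(sprintf("  planted DAE: both=%d, %s-only=%d, %s-only=%d (ratio %s:1)\n",
              x$planted_dae$both, x$conditions[1], x$planted_dae$a_only,
              x$conditions[2], x$planted_dae$b_only,
              format(x$planted_dae$ratio)))
  cat(sprintf("  intergenic background %.3f, rRNA admixture %.3f\n",
              x$intergenic_background_rate, sum(x$rrna_mix)))
  invisible(x)
}

#' Named simulation presets
#'
#' `"smoke"` is a tiny configuration for fast end-to-end checks.
#' `"paper_fig5"` mirrors the allelic architecture reported for the
#' heterozygous industrial strain: ~1,500 genes on 16 chromosomes, a
#' contiguous 140-gene fully monoallelic block spanning ~600 kb on the right
#' arm of chromosome 13 (LOH), 55 genes imbalanced 3:1 in both conditions,
#' 61 in condition TF only and 33 in condition FL only, all remaining genes
#' balanced, with informative coverage high enough that sampling noise cannot
#' flip a call. `"paper_fig1b_fl"` / `"paper_fig1b_tf"` are mock bacterial
#' communities in which Lactobacillaceae rRNA reads are planted so that
#' exactly 93% / 41% of them belong to *Lactobacillus fermentum*, alongside
#' two other families each holding at least 5% of the bacterial reads.
#'
#' @param name one of `"smoke"`, `"paper_fig5"`, `"paper_fig1b_fl"`,
#'   `"paper_fig1b_tf"`.
#' @return a [sim_config()] object.
#' @export
sim_preset <- function(name = c("smoke", "paper_fig5", "paper_fig1b_fl",
                                "paper_fig1b_tf")) {
  name <- match.arg(name)
  lacto <- "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;"
  fermentum <- paste0(lacto, "Lactobacillus_fermentum")
  delbrueckii <- paste0(lacto, "Lactobacillus_delbrueckii")
  aceto <- "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodospirillales;Acetobacteraceae;Acetobacter;Acetobacter_pasteurianus"
  bacillus <- "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus;Bacillus_subtilis"
  switch(name,
    smoke = sim_config(
      n_chromosomes = 2, genes_per_chromosome = 25,
      gene_length_bp = c(500, 900), snps_per_gene = c(1, 4),
      informative_depth = 80,
      planted_loh = list(chromosome = 2, n_genes = 12, span_bp = 60000,
                         haplotype = 1),
      planted_dae = list(both = 4, a_only = 3, b_only = 2, ratio = 3),
      intergenic_background_rate = 0.05,
      rrna_mix = stats::setNames(c(0.01, 0.01), c(fermentum, aceto)),
      seed = 101),
    paper_fig5 = sim_config(
      n_chromosomes = 16,
      genes_per_chromosome = c(rep(89L, 12), 160L, rep(89L, 3)),
      gene_length_bp = c(600, 1200), snps_per_gene = c(4, 8),
      informative_depth = 500,
      conditions = c("TF", "FL"),
      planted_loh = list(chromosome = 13, n_genes = 140, span_bp = 600000,
                         haplotype = 1),
      planted_dae = list(both = 55, a_only = 61, b_only = 33, ratio = 3),
      intergenic_background_rate = 0.02,
      rrna_mix = stats::setNames(c(0.002, 0.002), c(fermentum, aceto)),
      seed = 20090825),
    paper_fig1b_fl = sim_config(
      n_chromosomes = 2, genes_per_chromosome = 20,
      gene_length_bp = c(500, 900), snps_per_gene = c(0, 2),
      reads_per_library = 20000L, informative_depth = NULL,
      conditions = c("FL", "FL2"),
      planted_dae = list(both = 0, a_only = 0, b_only = 0, ratio = 3),
      intergenic_background_rate = 0.02,
      rrna_mix = stats::setNames(c(0.279, 0.021, 0.100, 0.100),
                                 c(fermentum, delbrueckii, aceto, bacillus)),
      seed = 3141),
    paper_fig1b_tf = sim_config(
      n_chromosomes = 2, genes_per_chromosome = 20,
      gene_length_bp = c(500, 900), snps_per_gene = c(0, 2),
      reads_per_library = 20000L, informative_depth = NULL,
      conditions = c("TF", "TF2"),
      planted_dae = list(both = 0, a_only = 0, b_only = 0, ratio = 3),
      intergenic_background_rate = 0.02,
      rrna_mix = stats::setNames(c(0.123, 0.177, 0.100, 0.100),
                                 c(fermentum, delbrueckii, aceto, bacillus)),
      seed = 3142))
}

## exact fraction of read start positions on a gene that overlap >=1 SNP
informative_fraction <- function(L, snp_pos, read_len) {
  n_starts <- L - read_len + 1
  if (length(snp_pos) == 0 || n_starts <= 0) return(0)
  lo <- pmax(1L, snp_pos - read_len + 1L)
  hi <- pmin(snp_pos, n_starts)
  keep <- lo <= hi
  if (!any(keep)) return(0)
  lo <- lo[keep]; hi <- hi[keep]
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  covered <- 0L
  cur_lo <- lo[1]; cur_hi <- hi[1]
  if (length(lo) > 1) for (i in 2:length(lo)) {
    if (lo[i] <= cur_hi + 1L) cur_hi <- max(cur_hi, hi[i])
    else { covered <- covered + cur_hi - cur_lo + 1L; cur_lo <- lo[i]; cur_hi <- hi[i] }
  }
  covered <- covered + cur_hi - cur_lo + 1L
  covered / n_starts
}

## SNP positions uniform on [1, L] subject to min spacing
sample_snp_positions <- function(k, L, spacing) {
  if (k == 0) return(integer(0))
  slack <- L - (k - 1) * spacing
  base <- sort(sample.int(slack, k))
  as.integer(base + (seq_len(k) - 1L) * spacing)
}

#' Build a synthetic reference bundle
#'
#' Generates, deterministically for a fixed seed, the full reference a run
#' needs: haplotype-1 gene sequences (the alignment reference) and their
#' haplotype-2 counterparts differing exactly at the phased SNP positions,
#' gene coordinates, intergenic regions (all longer than 500 bp, so each
#' qualifies for the background-threshold set), phased heterozygous SNPs
#' (haplotype 1 = REF), a lineage-labelled bacterial rRNA fragment set, and
#' the per-gene truth (role, major haplotype, true allele-1 fraction per
#' condition, LOH membership).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `aseloh_ref`: a list with elements `genes`,
#'   `snps`, `seq_h1`, `seq_h2`, `intergenic`, `intergenic_seq`, `rrna`,
#'   `config`.
#' @export
build_reference <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, build_reference_impl(config))
}

build_reference_impl <- function(cfg) {
  gpc <- rep_len(cfg$genes_per_chromosome, cfg$n_chromosomes)
  loh <- cfg$planted_loh
  rl <- cfg$read_length_bp

  genes <- list(); snps <- list(); seq_h1 <- character(0); seq_h2 <- character(0)
  inter <- list(); inter_seq <- character(0)
  gidx <- 0L; iidx <- 0L
  for (chr in seq_len(cfg$n_chromosomes)) {
    ng <- gpc[chr]
    lens <- sample(seq(cfg$gene_length_bp[1], cfg$gene_length_bp[2]), ng,
                   replace = TRUE)
    gaps <- sample(seq(cfg$intergenic_gap_bp[1], cfg$intergenic_gap_bp[2]), ng,
                   replace = TRUE) # gap before each gene
    in_block <- rep(FALSE, ng)
    if (!is.null(loh) && loh$chromosome == chr) {
      block <- (ng - loh$n_genes + 1L):ng
      in_block[block] <- TRUE
      ## calibrate block gaps so the span (first start .. last end) ~ span_bp
      block_len <- sum(lens[block])
      n_gap <- loh$n_genes - 1L
      if (n_gap > 0) {
        m <- (loh$span_bp - block_len) / n_gap
        if (m < cfg$intergenic_gap_bp[1])
          stop("planted_loh span too small for its gene count")
        g <- round(stats::runif(n_gap, 0.85 * m, 1.15 * m))
        gaps[block[-1]] <- pmax(as.integer(g), cfg$intergenic_gap_bp[1])
      }
    }
    pos <- 1L
    for (i in seq_len(ng)) {
      ## intergenic gap precedes every gene
      iidx <- iidx + 1L
      inter[[iidx]] <- data.frame(
        region_id = sprintf("ig%05d", iidx), chrom = sprintf("chr%02d", chr),
        start = pos, end = pos + gaps[i] - 1L, length = gaps[i],
        stringsAsFactors = FALSE)
      inter_seq[iidx] <- random_dna(gaps[i])
      pos <- pos + gaps[i]
      gidx <- gidx + 1L
      L <- lens[i]
      gene_id <- sprintf("g%05d", gidx)
      k <- sample(seq(cfg$snps_per_gene[1], cfg$snps_per_gene[2]), 1L)
      p <- sample_snp_positions(k, L, cfg$min_snp_spacing)
      s1 <- random_dna(L)
      b1 <- if (k > 0) substring(s1, p, p) else character(0)
      b2 <- vapply(b1, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                   "", USE.NAMES = FALSE)
      s2 <- subst_bases(s1, p, b2)
      seq_h1[gidx] <- s1; seq_h2[gidx] <- s2
      genes[[gidx]] <- data.frame(
        gene_id = gene_id, chrom = sprintf("chr%02d", chr),
        start = pos, end = pos + L - 1L, length = L, n_snps = k,
        loh = in_block[i], stringsAsFactors = FALSE)
      if (k > 0) snps[[length(snps) + 1L]] <- data.frame(
        gene_id = gene_id, chrom = sprintf("chr%02d", chr),
        pos = pos + p - 1L, local_pos = p, h1 = b1, h2 = b2,
        stringsAsFactors = FALSE)
      pos <- pos + L
    }
  }
  genes <- do.call(rbind, genes)
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(gene_id = character(0), chrom = character(0),
               pos = integer(0), local_pos = integer(0),
               h1 = character(0), h2 = character(0))
  names(seq_h1) <- genes$gene_id
  names(seq_h2) <- genes$gene_id
  inter <- do.call(rbind, inter)
  names(inter_seq) <- inter$region_id

  ## assign planted roles: DAE sets drawn off the LOH chromosome, disjoint,
  ## and only among genes with at least one SNP (a SNP-free gene cannot carry
  ## an allelic signal)
  genes$role <- ifelse(genes$loh, "loh", "balanced")
  dae <- cfg$planted_dae
  need <- dae$both + dae$a_only + dae$b_only
  if (need > 0) {
    loh_chr <- if (!is.null(loh)) sprintf("chr%02d", loh$chromosome) else ""
    pool <- which(genes$chrom != loh_chr & genes$n_snps > 0)
    if (length(pool) < need)
      stop("not enough SNP-bearing genes off the LOH chromosome for the ",
           "planted DAE sets")
    pick <- sample(pool, need)
    genes$role[pick[seq_len(dae$both)]] <- "dae_both"
    if (dae$a_only > 0)
      genes$role[pick[dae$both + seq_len(dae$a_only)]] <- "dae_a"
    if (dae$b_only > 0)
      genes$role[pick[dae$both + dae$a_only + seq_len(dae$b_only)]] <- "dae_b"
  }
  ## major haplotype: fixed for the LOH block, random for DAE genes
  genes$major_hap <- NA_integer_
  loh_hap <- if (!is.null(loh) && !is.null(loh$haplotype)) loh$haplotype else 1L
  genes$major_hap[genes$role == "loh"] <- loh_hap
  is_dae <- genes$role %in% c("dae_both", "dae_a", "dae_b")
  genes$major_hap[is_dae] <- sample(1:2, sum(is_dae), replace = TRUE)

  ## true allele-1 fraction per condition
  hi <- dae$ratio / (dae$ratio + 1)
  af_of <- function(role, major, which_cond) {
    af <- rep(0.5, length(role))
    imb <- role == "dae_both" |
      (role == "dae_a" & which_cond == 1L) |
      (role == "dae_b" & which_cond == 2L)
    af[imb] <- ifelse(major[imb] == 1L, hi, 1 - hi)
    af[role == "loh"] <- ifelse(major[role == "loh"] == 1L, 1, 0)
    af
  }
  for (ci in seq_along(cfg$conditions)) {
    wc <- min(ci, 2L) # conditions beyond the second behave like the second
    genes[[paste0("af_", cfg$conditions[ci])]] <-
      af_of(genes$role, genes$major_hap, wc)
  }

  ## expression: per-gene read counts
  if (!is.null(cfg$informative_depth)) {
    p_inf <- mapply(function(g, L) informative_fraction(
      L, snps$local_pos[snps$gene_id == g], rl),
      genes$gene_id, genes$length)
    genes$p_informative <- as.numeric(p_inf)
    er <- rep(ceiling(cfg$informative_depth), nrow(genes))
    has_snp <- p_inf > 0
    er[has_snp] <- ceiling(cfg$informative_depth / p_inf[has_snp])
    genes$expr_reads <- as.integer(er)
  } else {
    genes$p_informative <- mapply(function(g, L) informative_fraction(
      L, snps$local_pos[snps$gene_id == g], rl),
      genes$gene_id, genes$length)
    w <- stats::rlnorm(nrow(genes), meanlog = 0, sdlog = 1)
    genes$expr_reads <- NA_integer_ # resolved at simulation time from weights
    genes$expr_weight <- w / sum(w)
  }

  ## rRNA reference: a few unique fragments per species in the mix, plus one
  ## decoy species per family to keep classification honest
  lineages <- names(cfg$rrna_mix)
  rrna <- make_rrna_reference(lineages)

  structure(list(genes = genes, snps = snps, seq_h1 = seq_h1, seq_h2 = seq_h2,
                 intergenic = inter, intergenic_seq = inter_seq,
                 rrna = rrna, config = cfg),
            class = "aseloh_ref")
}

make_rrna_reference <- function(lineages, frags_per_species = 3L,
                                frag_len = c(200, 400)) {
  rows <- list()
  seqs <- character(0)
  n <- 0L
  for (lin in lineages) {
    for (j in seq_len(frags_per_species)) {
      n <- n + 1L
      L <- sample(seq(frag_len[1], frag_len[2]), 1L)
      rows[[n]] <- data.frame(frag_id = sprintf("rrna%04d", n),
                              lineage = lin, stringsAsFactors = FALSE)
      seqs[n] <- random_dna(L)
    }
  }
  ref <- do.call(rbind, rows)
  ref$seq <- seqs
  ref
}

#' @export
print.aseloh_ref <- function(x, ...) {
  cat(sprintf(
    "Synthetic reference: %d genes on %d chromosomes, %d phased SNPs,\n  %d intergenic regions (min %d bp), %d rRNA fragments (%d species)\n",
    nrow(x$genes), length(unique(x$genes$chrom)), nrow(x$snps),
    nrow(x$intergenic), min(x$intergenic$length), nrow(x$rrna),
    length(unique(x$rrna$lineage))))
  invisible(x)
}

#' Simulate one sequencing library
#'
#' Draws error-free single-end reads from a reference bundle: gene reads in
#' proportion to each gene's true expression, with the haplotype of every
#' read drawn from the gene's true allele-1 fraction for the requested
#' condition (fully monoallelic for planted LOH genes); a fixed fraction of
#' intergenic background reads; and an rRNA admixture whose per-species read
#' counts follow the configured composition exactly (largest-remainder
#' allocation, not multinomial sampling), so planted community fractions are
#' hit exactly.
#'
#' @param ref an `aseloh_ref` bundle from [build_reference()].
#' @param condition a condition label from `ref$config$conditions`.
#' @param seed optional integer; by default derived deterministically from
#'   the configuration seed and the condition label so conditions are
#'   independent but reproducible.
#' @return an object of class `aseloh_library`: list with `reads` (named
#'   character vector), `truth` (one row per read: `read_id`, `source`,
#'   `feature`, `haplotype`, `start`, `lineage`), `condition`, `seed`.
#' @export
simulate_library <- function(ref, condition, seed = NULL) {
  stopifnot(inherits(ref, "aseloh_ref"))
  cfg <- ref$config
  if (!condition %in% cfg$conditions)
    stop("unknown condition label: ", condition,
         " (configured: ", paste(cfg$conditions, collapse = ", "), ")")
  if (is.null(seed))
    seed <- as.integer((as.numeric(cfg$seed) * 1009 + str_seed(condition)) %%
                         2147483647)
  with_seed(seed, simulate_library_impl(ref, condition, seed))
}

simulate_library_impl <- function(ref, condition, seed) {
  cfg <- ref$config
  rl <- cfg$read_length_bp
  genes <- ref$genes
  af <- genes[[paste0("af_", condition)]]

  ## resolve the library composition
  bg_rate <- cfg$intergenic_background_rate
  rrna_frac <- cfg$rrna_mix
  if (!is.null(cfg$informative_depth)) {
    n_gene_target <- sum(genes$expr_reads)
    total <- as.integer(round(n_gene_target / (1 - bg_rate - sum(rrna_frac))))
  } else {
    if (is.na(cfg$reads_per_library))
      stop("reads_per_library must be set when informative_depth is NULL")
    total <- cfg$reads_per_library
  }
  side <- alloc_exact(total, c(rrna_frac, .background = bg_rate))
  n_rrna <- side[seq_along(rrna_frac)]
  n_bg <- side[[length(side)]]
  n_gene <- total - sum(side)

  if (!is.null(cfg$informative_depth)) {
    gq <- alloc_exact(n_gene, genes$expr_reads / sum(genes$expr_reads))
  } else {
    gq <- alloc_exact(n_gene, genes$expr_weight)
  }

  ## gene reads
  gi <- rep(seq_len(nrow(genes)), gq)
  starts <- integer(length(gi))
  hap <- integer(length(gi))
  offs <- stats::runif(length(gi))
  starts <- as.integer(1L + floor(offs * (genes$length[gi] - rl + 1L)))
  hap <- ifelse(stats::runif(length(gi)) < af[gi], 1L, 2L)
  seqs <- character(length(gi))
  h1_idx <- hap == 1L
  seqs[h1_idx] <- substring(ref$seq_h1[gi[h1_idx]], starts[h1_idx],
                            starts[h1_idx] + rl - 1L)
  seqs[!h1_idx] <- substring(ref$seq_h2[gi[!h1_idx]], starts[!h1_idx],
                             starts[!h1_idx] + rl - 1L)
  gene_truth <- data.frame(source = "gene",
                           feature = genes$gene_id[gi],
                           haplotype = hap, start = starts,
                           lineage = NA_character_,
                           stringsAsFactors = FALSE)

  ## intergenic background reads
  if (n_bg > 0) {
    ok <- ref$intergenic$length >= rl
    ii <- sample(which(ok), n_bg, replace = TRUE)
    istart <- as.integer(1L + floor(stats::runif(n_bg) *
                                      (ref$intergenic$length[ii] - rl + 1L)))
    iseq <- substring(ref$intergenic_seq[ii], istart, istart + rl - 1L)
    bg_truth <- data.frame(source = "intergenic",
                           feature = ref$intergenic$region_id[ii],
                           haplotype = NA_integer_, start = istart,
                           lineage = NA_character_, stringsAsFactors = FALSE)
  } else {
    iseq <- character(0); bg_truth <- NULL
  }

  ## rRNA admixture: species counts exact per the configured mix
  rseq <- character(0); rrna_truth <- NULL
  if (sum(n_rrna) > 0) {
    rows <- list(); k <- 0L
    rseq <- character(sum(n_rrna)); ri <- 0L
    for (s in seq_along(n_rrna)) {
      ns <- n_rrna[s]
      if (ns == 0) next
      lin <- names(cfg$rrna_mix)[s]
      frags <- which(ref$rrna$lineage == lin &
                       nchar(ref$rrna$seq) >= rl)
      fi <- frags[1L + floor(stats::runif(ns) * length(frags))]
      flen <- nchar(ref$rrna$seq[fi])
      fs <- as.integer(1L + floor(stats::runif(ns) * (flen - rl + 1L)))
      rseq[ri + seq_len(ns)] <- substring(ref$rrna$seq[fi], fs, fs + rl - 1L)
      ri <- ri + ns
      k <- k + 1L
      rows[[k]] <- data.frame(source = "rrna", feature = ref$rrna$frag_id[fi],
                              haplotype = NA_integer_, start = fs,
                              lineage = lin, stringsAsFactors = FALSE)
    }
    rrna_truth <- do.call(rbind, rows)
  }

  truth <- rbind(gene_truth, bg_truth, rrna_truth)
  truth$read_id <- sprintf("%s_r%07d", condition, seq_len(nrow(truth)))
  truth <- truth[, c("read_id", "source", "feature", "haplotype", "start",
                     "lineage")]
  reads <- c(seqs, iseq, rseq)
  names(reads) <- truth$read_id
  structure(list(reads = reads, truth = truth, condition = condition,
                 seed = seed, n_reads = length(reads)),
            class = "aseloh_library")
}

#' @export
print.aseloh_library <- function(x, ...) {
  tab <- table(x$truth$source)
  cat(sprintf("Simulated library '%s': %d reads (%s), seed %d\n",
              x$condition, x$n_reads,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$seed))
  invisible(x)
}
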
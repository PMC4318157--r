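## End-to-end driver: simulate -> align -> quantify -> threshold -> DE ->
## allele counting -> DAE -> LOH -> condition Venn -> rRNA taxonomy ->
## report, with deterministic seeds, per-stage TSV outputs and a run log.

log_stage <- function(con, stage, fmt, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Run the full analysis pipeline on a synthetic configuration
#'
#' Executes every stage on a freshly simulated dataset and writes one TSV
#' per stage (with the parameters echoed as `#` header comments) plus a
#' markdown report into `outdir`. Rerunning with the same configuration and
#' seed reproduces identical outputs.
#'
#' @param config a [sim_config()], or a preset name for [sim_preset()].
#' @param outdir output directory.
#' @param seed optional integer overriding the configuration seed.
#' @param quantile intergenic background quantile (default 0.95).
#' @param alpha,min_ratio_de differential-expression criteria (0.01, 2).
#' @param min_depth,min_ratio_dae DAE calling knobs (20, 2).
#' @param mono_fraction,min_genes,max_uninformative_gap LOH run-detection
#'   knobs (0.95, 10, 2).
#' @param family_cutoff minimum family fraction of bacterial reads (0.05).
#' @param write_reads also write per-condition FASTQ files and full truth
#'   tables (off by default; they dominate the run's disk footprint).
#' @return an object of class `aseloh_run`: all stage results plus file
#'   paths.
#' @export
run_pipeline <- function(config = "smoke", outdir = tempfile("aseloh_"),
                         seed = NULL, quantile = 0.95,
                         alpha = 0.01, min_ratio_de = 2,
                         min_depth = 20, min_ratio_dae = 2,
                         mono_fraction = 0.95, min_genes = 10,
                         max_uninformative_gap = 2, family_cutoff = 0.05,
                         write_reads = FALSE) {
  if (is.character(config)) config <- sim_preset(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) { config$seed <- as.integer(seed) }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logf))
  params <- list(seed = config$seed, quantile = quantile, alpha = alpha,
                 min_ratio_de = min_ratio_de, min_depth = min_depth,
                 min_ratio_dae = min_ratio_dae, mono_fraction = mono_fraction,
                 min_genes = min_genes,
                 max_uninformative_gap = max_uninformative_gap,
                 family_cutoff = family_cutoff)

  conds <- config$conditions[1:2]
  log_stage(logf, "simulate", "seed %d, conditions %s", config$seed,
            paste(conds, collapse = "/"))
  ref <- build_reference(config)
  write_reference_bundle(ref, file.path(outdir, "reference"))
  libs <- lapply(conds, function(cc) simulate_library(ref, cc))
  names(libs) <- conds
  for (cc in conds) {
    log_stage(logf, "simulate", "%s: %d reads (seed %d)", cc,
              libs[[cc]]$n_reads, libs[[cc]]$seed)
    if (write_reads) {
      write_fastq(libs[[cc]], file.path(outdir, paste0(cc, ".fastq")))
      utils::write.table(libs[[cc]]$truth,
                         file.path(outdir, paste0(cc, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## align to the gene + intergenic reference
  target <- c(ref$seq_h1, ref$intergenic_seq)
  aligns <- lapply(conds, function(cc) {
    a <- align_reads(libs[[cc]]$reads, target)
    log_stage(logf, "align", "%s: %d unique, %d repeat, %d unaligned", cc,
              sum(a$status == "unique"), sum(a$status == "repeat"),
              sum(a$status == "unaligned"))
    a
  })
  names(aligns) <- conds

  ## quantify
  gene_ids <- ref$genes$gene_id
  counts <- lapply(conds, function(cc)
    count_per_gene(aligns[[cc]], gene_ids, ref$intergenic$region_id,
                   library_id = cc))
  names(counts) <- conds
  rpkm_mat <- vapply(conds, function(cc)
    rpkm(counts[[cc]]$counts, ref$genes$length, counts[[cc]]$N),
    numeric(length(gene_ids)))
  rownames(rpkm_mat) <- gene_ids
  count_mat <- vapply(conds, function(cc) counts[[cc]]$counts,
                      integer(length(gene_ids)))
  write_tsv_report(data.frame(gene_id = gene_ids, count_mat),
                   file.path(outdir, "counts.tsv"), params["seed"])
  write_tsv_report(data.frame(gene_id = gene_ids, round(rpkm_mat, 4)),
                   file.path(outdir, "rpkm.tsv"), params["seed"])

  ## intergenic background thresholds
  thresholds <- lapply(conds, function(cc) {
    ig <- rpkm(counts[[cc]]$intergenic_counts, ref$intergenic$length,
               counts[[cc]]$N)
    estimate_background_threshold(ig, quantile = quantile, library_id = cc)
  })
  names(thresholds) <- conds
  thr_df <- data.frame(
    library_id = conds,
    threshold_rpkm = vapply(thresholds, `[[`, 0, "threshold"),
    quantile = quantile,
    n_regions = vapply(thresholds, `[[`, 0L, "n_regions"))
  write_tsv_report(thr_df, file.path(outdir, "thresholds.tsv"),
                   params[c("seed", "quantile")])
  for (cc in conds)
    log_stage(logf, "threshold", "%s: RPKM %.4g", cc,
              thresholds[[cc]]$threshold)
  expressed <- filter_expressed(rpkm_mat, thresholds)

  ## two-library differential expression between the conditions
  de <- de_two_library(count_mat[, 1], counts[[1]]$N,
                       count_mat[, 2], counts[[2]]$N,
                       gene_ids = gene_ids, alpha = alpha,
                       min_ratio = min_ratio_de,
                       expressed1 = expressed[, 1],
                       expressed2 = expressed[, 2])
  de_tab <- tabulate_de(de)
  log_stage(logf, "de", "%d DE genes (%d up, %d down)", de_tab$total,
            de_tab$up, de_tab$down)
  write_tsv_report(de, file.path(outdir, "de.tsv"),
                   params[c("seed", "alpha", "min_ratio_de")])
  write_tsv_report(data.frame(comparison = paste(conds, collapse = "_vs_"),
                              total = de_tab$total, up = de_tab$up,
                              down = de_tab$down),
                   file.path(outdir, "de_summary.tsv"), NULL)

  ## allele-specific expression
  allele_counts <- list(); dae <- list()
  coord <- ref$genes[, c("gene_id", "chrom", "start", "end")]
  for (cc in conds) {
    asg <- assign_read_haplotypes(aligns[[cc]], libs[[cc]]$reads, ref$snps)
    rec <- accumulate_gene_alleles(asg, cc, gene_ids = gene_ids)
    allele_counts[[cc]] <- rec
    calls <- call_dae(rec, min_depth = min_depth, min_ratio = min_ratio_dae)
    calls <- merge(calls, coord, by = "gene_id", sort = FALSE)
    calls <- calls[order(calls$chrom, calls$start), ]
    rownames(calls) <- NULL
    dae[[cc]] <- calls
    log_stage(logf, "ase", "%s: %d DAE calls of %d informative genes", cc,
              sum(calls$call %in% c("allele1", "allele2")),
              sum(calls$call != "uninformative"))
  }
  write_tsv_report(do.call(rbind, unname(allele_counts)),
                   file.path(outdir, "allele_counts.tsv"), params["seed"])
  write_tsv_report(do.call(rbind, unname(dae)),
                   file.path(outdir, "dae_calls.tsv"),
                   params[c("seed", "min_depth", "min_ratio_dae")])

  ## LOH runs on the first condition's calls, per chromosome
  segs <- do.call(rbind, lapply(split(dae[[1]], dae[[1]]$chrom), function(d)
    detect_loh_runs(d, mono_fraction = mono_fraction, min_genes = min_genes,
                    max_uninformative_gap = max_uninformative_gap)))
  rownames(segs) <- NULL
  class(segs) <- c("loh_segments", "data.frame")
  log_stage(logf, "loh", "%d segment(s)", nrow(segs))
  write_tsv_report(segs, file.path(outdir, "loh_segments.tsv"),
                   params[c("seed", "mono_fraction", "min_genes",
                            "max_uninformative_gap")])

  ## condition comparison (Venn), before and after excluding the LOH arm
  venn_before <- compare_conditions(dae[[1]], dae[[2]])
  venn_after <- venn_before
  excluded_chrom <- NA_character_; excluded_from <- NA_integer_
  if (nrow(segs) > 0) {
    top <- segs[which.max(segs$gene_count), ]
    excluded_chrom <- top$chrom; excluded_from <- top$start
    d1 <- exclude_region(dae[[1]], top$chrom, top$start)
    d2 <- exclude_region(dae[[2]], top$chrom, top$start)
    venn_after <- compare_conditions(d1, d2)
  }
  log_stage(logf, "venn",
            "before exclusion: both=%d %s=%d %s=%d; after: both=%d",
            length(venn_before$both), conds[1], length(venn_before$a_only),
            conds[2], length(venn_before$b_only), length(venn_after$both))
  venn_df <- data.frame(
    stage = c("before_exclusion", "after_exclusion"),
    both = c(length(venn_before$both), length(venn_after$both)),
    a_only = c(length(venn_before$a_only), length(venn_after$a_only)),
    b_only = c(length(venn_before$b_only), length(venn_after$b_only)))
  names(venn_df)[3:4] <- c(paste0(conds[1], "_only"),
                           paste0(conds[2], "_only"))
  write_tsv_report(venn_df, file.path(outdir, "venn.tsv"),
                   list(seed = config$seed, excluded_chrom = excluded_chrom,
                        excluded_from = excluded_from))

  ## taxonomy of reads that failed gene/intergenic alignment
  taxa <- NULL
  if (nrow(ref$rrna) > 0) {
    residual <- unlist(lapply(conds, function(cc) {
      un <- aligns[[cc]]$status == "unaligned"
      libs[[cc]]$reads[un]
    }))
    cls <- classify_reads(residual, ref$rrna)
    fam <- counts_per_taxon(cls, "family")
    spc <- counts_per_taxon(cls, "species")
    fam_kept <- apply_family_cutoff(fam, min_fraction = family_cutoff)
    fam$retained <- fam$taxon %in% fam_kept$taxon
    taxa <- list(classifications = cls, family = fam, species = spc,
                 retained = fam_kept)
    log_stage(logf, "taxa", "%d residual reads, %d classified, %d famil%s kept",
              nrow(cls), sum(cls$assigned), nrow(fam_kept),
              if (nrow(fam_kept) == 1) "y" else "ies")
    write_tsv_report(fam, file.path(outdir, "taxa_family.tsv"),
                     params[c("seed", "family_cutoff")])
    write_tsv_report(spc, file.path(outdir, "taxa_species.tsv"),
                     params["seed"])
  }

  run <- structure(list(
    config = config, outdir = outdir, params = params, ref = ref,
    libraries = libs, alignments = aligns, counts = counts,
    rpkm = rpkm_mat, thresholds = thresholds, expressed = expressed,
    de = de, allele_counts = allele_counts, dae = dae, loh = segs,
    venn_before = venn_before, venn_after = venn_after,
    excluded = list(chrom = excluded_chrom, from = excluded_from),
    taxa = taxa), class = "aseloh_run")
  make_report(outdir)
  log_stage(logf, "report", "written to %s", file.path(outdir, "report.md"))
  run
}

#' @export
print.aseloh_run <- function(x, ...) {
  cat(sprintf("aseloh run in %s\n", x$outdir))
  cat(sprintf("  genes %d, conditions %s\n", nrow(x$ref$genes),
              paste(names(x$libraries), collapse = "/")))
  t <- tabulate_de(x$de)
  cat(sprintf("  DE: %d (%d up, %d down)\n", t$total, t$up, t$down))
  cat(sprintf("  DAE Venn (after exclusion): both=%d, %s=%d, %s=%d\n",
              length(x$venn_after$both), names(x$libraries)[1],
              length(x$venn_after$a_only), names(x$libraries)[2],
              length(x$venn_after$b_only)))
  if (nrow(x$loh))
    cat(sprintf("  longest LOH run: %d genes, %.0f kb on %s\n",
                max(x$loh$gene_count),
                x$loh$span_bp[which.max(x$loh$gene_count)] / 1000,
                x$loh$chrom[which.max(x$loh$gene_count)]))
  invisible(x)
}

read_stage_tsv <- function(path) {
  if (!file.exists(path)) return(NULL)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a human-readable run summary
#'
#' Builds `report.md` from the stage TSVs found in `outdir`: expressed-gene
#' counts per library, DE totals, the DAE Venn partition, LOH segments and
#' the family-level taxon table with cutoff flags. Missing stages are
#' marked absent rather than failing.
#'
#' @param outdir a [run_pipeline()] output directory.
#' @return the report path, invisibly.
#' @export
make_report <- function(outdir) {
  out <- file.path(outdir, "report.md")
  lines <- c("# aseloh pipeline report", "")
  thr <- read_stage_tsv(file.path(outdir, "thresholds.tsv"))
  rp <- read_stage_tsv(file.path(outdir, "rpkm.tsv"))
  lines <- c(lines, "## Expressed genes per library", "")
  if (is.null(thr) || is.null(rp)) {
    lines <- c(lines, "(absent)", "")
  } else {
    for (i in seq_len(nrow(thr))) {
      lib <- thr$library_id[i]
      n_exp <- sum(rp[[lib]] >= thr$threshold_rpkm[i])
      lines <- c(lines, sprintf(
        "- %s: %d of %d genes at or above the background threshold (RPKM %.4g)",
        lib, n_exp, nrow(rp), thr$threshold_rpkm[i]))
    }
    lines <- c(lines, "")
  }
  des <- read_stage_tsv(file.path(outdir, "de_summary.tsv"))
  lines <- c(lines, "## Differential expression", "")
  lines <- c(lines, if (is.null(des)) "(absent)" else
    sprintf("- %s: %d DE genes (%d up, %d down)", des$comparison[1],
            des$total[1], des$up[1], des$down[1]), "")
  venn <- read_stage_tsv(file.path(outdir, "venn.tsv"))
  lines <- c(lines, "## Differential allelic expression (Venn)", "")
  if (is.null(venn)) lines <- c(lines, "(absent)", "") else {
    for (i in seq_len(nrow(venn)))
      lines <- c(lines, sprintf("- %s: both=%d, %s=%d, %s=%d", venn$stage[i],
                                venn$both[i], names(venn)[3], venn[[3]][i],
                                names(venn)[4], venn[[4]][i]))
    lines <- c(lines, "")
  }
  segs <- read_stage_tsv(file.path(outdir, "loh_segments.tsv"))
  lines <- c(lines, "## LOH segments", "")
  if (is.null(segs)) lines <- c(lines, "(absent)", "")
  else if (nrow(segs) == 0) lines <- c(lines, "- none detected", "")
  else {
    for (i in seq_len(nrow(segs)))
      lines <- c(lines, sprintf(
        "- %s:%d-%d — %d consecutive monoallelic genes, %.1f kb, haplotype %d",
        segs$chrom[i], segs$start[i], segs$end[i], segs$gene_count[i],
        segs$span_bp[i] / 1000, segs$dominant_haplotype[i]))
    lines <- c(lines, "")
  }
  fam <- read_stage_tsv(file.path(outdir, "taxa_family.tsv"))
  spc <- read_stage_tsv(file.path(outdir, "taxa_species.tsv"))
  lines <- c(lines, "## Bacterial rRNA profile (family level)", "")
  if (is.null(fam)) lines <- c(lines, "(absent)", "") else {
    kept <- fam[fam$retained & fam$taxon != "unresolved", , drop = FALSE]
    for (i in seq_len(nrow(kept))) {
      fam_line <- sprintf("- %s: %d reads (%.1f%%)", kept$taxon[i],
                          kept$count[i], 100 * kept$fraction[i])
      if (!is.null(spc)) {
        fam_of <- vapply(strsplit(spc$lineage, ";", fixed = TRUE),
                         function(v) if (length(v) >= 5) v[5] else NA, "")
        sp <- spc[!is.na(fam_of) & fam_of == kept$taxon[i], , drop = FALSE]
        if (nrow(sp)) {
          top <- sp[which.max(sp$count), ]
          fam_line <- paste0(fam_line, sprintf(
            "; dominant species %s (%.1f%% of family reads)", top$taxon,
            100 * top$count / sum(sp$count)))
        }
      }
      lines <- c(lines, fam_line)
    }
    lines <- c(lines, "")
  }
  writeLines(lines, out)
  invisible(out)
}
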
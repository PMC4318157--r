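## Readers and writers for the standard formats the pipeline exchanges:
## FASTA via Biostrings, GFF3 via rtracklayer, VCF 4.2 (phased "0|1",
## haplotype 1 = REF), FASTQ with fixed quality, TSV truth tables.

#' Write a reference bundle to disk
#'
#' Emits `genes.fa` (haplotype-1 gene sequences, the alignment reference),
#' `genes.gff3` (1-based inclusive, genes on '+'), `intergenic.fa`,
#' `snps.vcf` (phased GT `0|1`, haplotype 1 in the REF column),
#' `rrna.fa` (semicolon-delimited lineage in the description) and
#' `gene_truth.tsv`.
#'
#' @param ref an `aseloh_ref` from [build_reference()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(ref, dir) {
  stopifnot(inherits(ref, "aseloh_ref"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- Biostrings::DNAStringSet(ref$seq_h1)
  Biostrings::writeXStringSet(g, file.path(dir, "genes.fa"))
  ig <- Biostrings::DNAStringSet(ref$intergenic_seq)
  Biostrings::writeXStringSet(ig, file.path(dir, "intergenic.fa"))
  rr <- Biostrings::DNAStringSet(ref$rrna$seq)
  names(rr) <- paste(ref$rrna$frag_id, ref$rrna$lineage)
  Biostrings::writeXStringSet(rr, file.path(dir, "rrna.fa"))

  gr <- GenomicRanges::GRanges(
    seqnames = ref$genes$chrom,
    ranges = IRanges::IRanges(start = ref$genes$start, end = ref$genes$end),
    strand = "+", type = "gene", ID = ref$genes$gene_id)
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "gff3")

  write_phased_vcf(ref$snps, file.path(dir, "snps.vcf"))
  utils::write.table(ref$genes, file.path(dir, "gene_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

write_phased_vcf <- function(snps, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=aseloh-synthetic",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample1"),
             con)
  if (nrow(snps) > 0) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tGENE=%s\tGT\t0|1",
                       snps$chrom, snps$pos,
                       sprintf("snp%05d", seq_len(nrow(snps))),
                       snps$h1, snps$h2, snps$gene_id), con)
  }
  invisible(path)
}

#' Read a phased-SNP VCF
#'
#' Parses a VCF with phased `0|1` genotypes into the SNP table used by the
#' allelic analysis (haplotype 1 = REF). Unphased or non-`0|1` records are
#' dropped with a warning.
#'
#' @param path VCF file.
#' @return data.frame with columns `chrom`, `pos`, `h1`, `h2` and, when the
#'   INFO field carries `GENE=`, `gene_id`.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  phased <- if (!is.null(gt) && ncol(gt) >= 2)
    grepl("^0\\|1", gt[, 2]) else rep(TRUE, nrow(fix))
  if (any(!phased)) {
    warning(sum(!phased), " non-phased (not 0|1) records dropped")
    fix <- fix[phased, , drop = FALSE]
  }
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    h1 = fix$REF, h2 = fix$ALT, stringsAsFactors = FALSE)
  gene <- sub("^.*GENE=([^;]+).*$", "\\1", fix$INFO)
  if (length(gene) && !all(gene == fix$INFO)) out$gene_id <- gene
  out
}

#' Write simulated reads as FASTQ
#'
#' Fixed quality 'I' for every base (error-free reads).
#'
#' @param lib an `aseloh_library` (or a named character vector of reads).
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lib, path) {
  reads <- if (inherits(lib, "aseloh_library")) lib$reads else lib
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
  con <- file(path, open = "wt")
  on.exit(close(con))
  chunk <- 200000L
  for (i in seq(1L, length(reads), by = chunk)) {
    j <- min(i + chunk - 1L, length(reads))
    block <- rbind(paste0("@", ids[i:j]), reads[i:j], "+",
                   strrep("I", nchar(reads[i:j])))
    writeLines(as.vector(block), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub(" .*$", "", names(x)))
}

#' Read a lineage-labelled rRNA FASTA
#'
#' Headers follow the SILVA convention: an identifier, whitespace, then a
#' semicolon-delimited taxonomy string (domain;phylum;...;species).
#'
#' @param path FASTA path.
#' @return data.frame with columns `frag_id`, `lineage`, `seq`.
#' @export
read_lineage_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  data.frame(frag_id = sub("\\s.*$", "", hdr),
             lineage = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
             seq = as.character(x), stringsAsFactors = FALSE)
}

#' Read gene models from GFF3
#' @param path GFF3 path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `length`.
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = gr$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             length = GenomicRanges::width(gr), stringsAsFactors = FALSE)
}

#' Read alignments from a SAM file
#'
#' Accepts output of any external aligner in place of the built-in matcher.
#' Only single-end, mapped, primary records are kept; the mismatch count is
#' taken from the `NM` tag when present.
#'
#' @param path SAM (text) path.
#' @return data.frame compatible with [align_reads()] output: `read_id`,
#'   `feature`, `pos`, `mismatches`, `status`.
#' @export
read_sam_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(read_id = character(0), feature = character(0),
                      pos = integer(0), mismatches = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[`, "", 1L)
  flag <- as.integer(vapply(f, `[`, "", 2L))
  rname <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L))
  nm <- vapply(f, function(v) {
    t <- grep("^NM:i:", v, value = TRUE)
    if (length(t)) as.integer(sub("^NM:i:", "", t[1])) else NA_integer_
  }, 1L)
  mapped <- bitwAnd(flag, 4L) == 0L & !bitwAnd(flag, 256L) &
    !bitwAnd(flag, 2048L) & rname != "*"
  data.frame(read_id = qname,
             feature = ifelse(mapped, rname, NA_character_),
             pos = ifelse(mapped, pos, NA_integer_),
             mismatches = ifelse(mapped, nm, NA_integer_),
             status = ifelse(mapped, "unique", "unaligned"),
             stringsAsFactors = FALSE)
}
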
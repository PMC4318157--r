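## Taxonomic profiling of residual rRNA reads: classification against a
## lineage-labelled reference (unique best hit, ties salvaged by lowest
## common ancestor), per-rank aggregation, the 5% family cutoff and
## within-family species fractions.

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

#' Parse a semicolon-delimited lineage string
#'
#' @param lineage e.g.
#'   `"Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus_fermentum"`.
#'   Trailing ranks may be absent (unresolved).
#' @return character vector of length 7 named by rank, `NA` where
#'   unresolved.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  out <- rep(NA_character_, length(TAX_RANKS))
  names(out) <- TAX_RANKS
  n <- min(length(parts), length(TAX_RANKS))
  out[seq_len(n)] <- parts[seq_len(n)]
  out
}

lineage_lca <- function(lineages) {
  mats <- vapply(lineages, parse_lineage, character(length(TAX_RANKS)))
  keep <- apply(mats, 1, function(r) !anyNA(r) && length(unique(r)) == 1)
  depth <- if (any(!keep)) min(which(!keep)) - 1L else length(TAX_RANKS)
  if (depth == 0) return("")
  paste(mats[seq_len(depth), 1], collapse = ";")
}

#' Classify rRNA reads against a lineage-labelled reference
#'
#' Reads are matched with the built-in unique-best matcher (up to
#' `max_mismatches` mismatches). A unique best hit inherits that fragment's
#' full lineage. A read tied between fragments is, by default, salvaged at
#' their lowest common ancestor rank when the tied lineages still agree
#' below domain, and discarded otherwise; `strict = TRUE` discards every
#' tied read (the original pipeline's pure repeat-discarding). Reads with
#' no hit within the mismatch budget are unassigned.
#'
#' @param reads named character vector (or `aseloh_library`, or FASTQ
#'   path).
#' @param reference data.frame with `frag_id`, `lineage`, `seq` (see
#'   [read_lineage_fasta()]), or a lineage-labelled FASTA path.
#' @param max_mismatches mismatch budget (default 2).
#' @param strict discard all tied reads instead of applying the LCA rule.
#' @return data.frame with one row per read: `read_id`, `assigned`,
#'   `lineage` (possibly rank-truncated; `NA` when unassigned).
#' @export
classify_reads <- function(reads, reference, max_mismatches = 2,
                           strict = FALSE) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference))
    reference <- read_lineage_fasta(reference)
  stopifnot(all(c("frag_id", "lineage", "seq") %in% names(reference)))
  if (nrow(reference) == 0) stop("empty rRNA reference")
  refseq <- stats::setNames(reference$seq, reference$frag_id)
  al <- align_reads(reads, refseq, max_mismatches = max_mismatches,
                    report_ties = TRUE)
  lin <- rep(NA_character_, nrow(al))
  uq <- al$status == "unique"
  lin[uq] <- reference$lineage[match(al$feature[uq], reference$frag_id)]
  if (!strict) {
    rp <- which(al$status == "repeat")
    for (i in rp) {
      feats <- strsplit(al$tied_features[i], ",", fixed = TRUE)[[1]]
      tied <- unique(reference$lineage[as.integer(feats)])
      lca <- lineage_lca(tied)
      ## ties agreeing only at domain (or not at all) stay discarded
      if (nzchar(lca) && length(strsplit(lca, ";")[[1]]) >= 2) lin[i] <- lca
    }
  }
  data.frame(read_id = al$read_id, assigned = !is.na(lin), lineage = lin,
             stringsAsFactors = FALSE)
}

#' Tally classified reads per taxon at a rank
#'
#' Reads whose lineage is unresolved at the requested rank are reported in
#' an `"unresolved"` bucket; fractions are over all classified reads.
#'
#' @param classifications data.frame from [classify_reads()] (or a
#'   character vector of lineages, `NA` = unassigned).
#' @param rank one of domain, phylum, class, order, family, genus, species.
#' @return data.frame of class `taxon_counts`: `taxon`, `rank`, `lineage`
#'   (prefix up to the rank), `count`, `fraction`.
#' @export
counts_per_taxon <- function(classifications, rank = "family") {
  rank <- match.arg(rank, TAX_RANKS)
  ri <- match(rank, TAX_RANKS)
  lineages <- if (is.data.frame(classifications))
    classifications$lineage[classifications$assigned] else
      classifications[!is.na(classifications)]
  if (length(lineages) == 0)
    return(structure(data.frame(taxon = character(0), rank = character(0),
                                lineage = character(0), count = integer(0),
                                fraction = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("taxon_counts", "data.frame")))
  prefix <- vapply(lineages, function(l) {
    p <- parse_lineage(l)
    if (is.na(p[ri])) "unresolved" else paste(p[seq_len(ri)], collapse = ";")
  }, "", USE.NAMES = FALSE)
  tab <- sort(table(prefix), decreasing = TRUE)
  taxon <- vapply(strsplit(names(tab), ";", fixed = TRUE),
                  function(v) v[length(v)], "")
  out <- data.frame(taxon = taxon, rank = rank, lineage = names(tab),
                    count = as.integer(tab),
                    fraction = as.integer(tab) / length(lineages),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("taxon_counts", class(out))
  out
}

#' Apply the minimum family-abundance cutoff
#'
#' Families holding less than `min_fraction` of the classified bacterial
#' reads are dropped from further analysis; the boundary (exactly the
#' cutoff) is retained. The `"unresolved"` bucket is never retained.
#'
#' @param family_counts a `taxon_counts` data.frame at rank family.
#' @param min_fraction abundance cutoff (default 0.05).
#' @return the retained subset, with a `retained` column echoing the rule.
#' @export
apply_family_cutoff <- function(family_counts, min_fraction = 0.05) {
  keep <- family_counts$fraction >= min_fraction &
    family_counts$taxon != "unresolved"
  out <- family_counts[keep, , drop = FALSE]
  out$retained <- TRUE
  rownames(out) <- NULL
  out
}

#' Within-family species fraction
#'
#' The share of a family's classified reads that belong to one species
#' (e.g. the fraction of Lactobacillaceae reads assigned to
#' *Lactobacillus fermentum*).
#'
#' @param species_counts a `taxon_counts` data.frame at rank species.
#' @param family family name.
#' @param species species name.
#' @return fraction in `[0, 1]`.
#' @export
species_fraction <- function(species_counts, family, species) {
  stopifnot(inherits(species_counts, "data.frame"))
  fam_of <- vapply(strsplit(species_counts$lineage, ";", fixed = TRUE),
                   function(v) if (length(v) >= 5) v[5] else NA_character_,
                   "")
  in_fam <- !is.na(fam_of) & fam_of == family
  fam_total <- sum(species_counts$count[in_fam])
  if (fam_total == 0) stop("family has no classified reads: ", family)
  sum(species_counts$count[in_fam & species_counts$taxon == species]) /
    fam_total
}
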
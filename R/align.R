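## Built-in short-read matcher with the aligner contract of the original
## analysis: up to two base mismatches, unique-best placements only (reads
## whose best score is achieved at more than one location are discarded as
## repeats). Implemented as a seed-and-extend search in C++ (three disjoint
## k-mer seeds; by pigeonhole a read with <= 2 mismatches has at least one
## exact seed).

#' Align reads against a feature-indexed reference
#'
#' Each read yields at most one alignment: its unique best placement with at
#' most `max_mismatches` mismatches across all features and offsets. Reads
#' whose best score is reached at more than one (feature, offset) location
#' are discarded as repeats; reads with no placement within the mismatch
#' budget are unaligned.
#'
#' @param reads named character vector of read sequences, an
#'   `aseloh_library`, or a FASTQ path.
#' @param reference named character vector or `Biostrings::DNAStringSet` of
#'   feature sequences (genes, intergenic regions, rRNA fragments, ...).
#' @param max_mismatches mismatch budget (default 2).
#' @param report_ties keep the tied feature list for repeat reads (used by
#'   the taxonomic classifier's lowest-common-ancestor rule).
#' @return data.frame with one row per read: `read_id`, `feature` (NA when
#'   not uniquely aligned), `pos` (1-based offset within the feature),
#'   `mismatches`, `status` (`unique` / `repeat` / `unaligned`), `n_best`,
#'   and `tied_features` when `report_ties`.
#' @export
align_reads <- function(reads, reference, max_mismatches = 2,
                        report_ties = FALSE) {
  if (inherits(reads, "aseloh_library")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
      grepl("\\.(fastq|fq)$", reads))
    reads <- read_fastq(reads)
  if (inherits(reference, "DNAStringSet")) {
    nm <- names(reference)
    reference <- stats::setNames(as.character(reference), nm)
  }
  if (length(reference) == 0) stop("empty reference")
  if (is.null(names(reference)))
    names(reference) <- sprintf("feat%04d", seq_along(reference))
  if (length(reads) == 0)
    return(data.frame(read_id = character(0), feature = character(0),
                      pos = integer(0), mismatches = integer(0),
                      status = character(0), n_best = integer(0),
                      stringsAsFactors = FALSE))
  if (min(nchar(reads)) > max(nchar(reference)))
    stop("every read is longer than every reference feature")
  res <- .cpp_align_reads(unname(reads), unname(reference),
                          as.integer(max_mismatches), report_ties)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
  out <- data.frame(read_id = ids,
                    feature = names(reference)[res$feature],
                    pos = res$pos, mismatches = res$mismatches,
                    status = res$status, n_best = res$n_best,
                    stringsAsFactors = FALSE)
  if (report_ties) out$tied_features <- res$tied_features
  out
}
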
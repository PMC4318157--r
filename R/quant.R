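## Expression quantification: per-gene read counting, RPKM, the
## intergenic-background RPKM threshold, expressed-gene flags, and the
## 2^-ddCT qPCR utility.

#' Tally aligned reads per gene (and per intergenic region)
#'
#' Exact tallies of uniquely aligned reads. `N`, the library size used by
#' the RPKM formula, is the total number of reads aligned to genes.
#'
#' @param alignments data.frame from [align_reads()] (or
#'   [read_sam_alignments()]).
#' @param gene_ids character vector of gene feature ids (the count vector is
#'   returned in this order, zero-filled).
#' @param intergenic_ids optional character vector of intergenic feature
#'   ids.
#' @param library_id label for this library.
#' @return an object of class `library_counts`: list with `library_id`,
#'   `counts` (named integer), `N`, `intergenic_counts`.
#' @export
count_per_gene <- function(alignments, gene_ids, intergenic_ids = NULL,
                           library_id = "lib1") {
  ok <- alignments$status == "unique" & !is.na(alignments$feature)
  feat <- alignments$feature[ok]
  unknown <- setdiff(unique(feat), c(gene_ids, intergenic_ids))
  if (length(unknown))
    stop("alignments reference unknown features, e.g. ", unknown[1])
  tab <- table(factor(feat[feat %in% gene_ids], levels = gene_ids))
  counts <- stats::setNames(as.integer(tab), gene_ids)
  icounts <- NULL
  if (!is.null(intergenic_ids)) {
    itab <- table(factor(feat[feat %in% intergenic_ids],
                         levels = intergenic_ids))
    icounts <- stats::setNames(as.integer(itab), intergenic_ids)
  }
  structure(list(library_id = library_id, counts = counts,
                 N = sum(counts), intergenic_counts = icounts),
            class = "library_counts")
}

#' @export
print.library_counts <- function(x, ...) {
  cat(sprintf("Library '%s': %d reads on %d genes", x$library_id, x$N,
              length(x$counts)))
  if (!is.null(x$intergenic_counts))
    cat(sprintf("; %d on %d intergenic regions",
                sum(x$intergenic_counts), length(x$intergenic_counts)))
  cat("\n")
  invisible(x)
}

#' Reads per kilobase per million aligned reads
#'
#' `RPKM = 1e9 * C / (N * L)` where `C` is the read count on the feature,
#' `L` its length in bp and `N` the total reads aligned to genes in the
#' library. Vectorised over `C` and `L`.
#'
#' @param C non-negative read count(s).
#' @param L feature length(s), bp, > 0.
#' @param N total aligned reads, > 0.
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6) # 10
#' @export
rpkm <- function(C, L, N) {
  if (any(N <= 0)) stop("N (total aligned reads) must be positive")
  if (any(L <= 0)) stop("L (feature length) must be positive")
  if (any(C < 0)) stop("counts must be non-negative")
  1e9 * as.numeric(C) / (as.numeric(N) * as.numeric(L))
}

#' Estimate the intergenic-background RPKM threshold
#'
#' Replaces the original study's "visual inspection" of the gene and
#' intergenic RPKM distributions with a reproducible rule: the nearest-rank
#' empirical quantile of the intergenic-region RPKM distribution.
#'
#' @param intergenic_rpkm numeric vector of RPKM values over intergenic
#'   regions (each longer than 500 bp).
#' @param quantile quantile used (default 0.95).
#' @param library_id label.
#' @return object of class `background_threshold`: list with `library_id`,
#'   `threshold`, `quantile`, `n_regions`.
#' @export
estimate_background_threshold <- function(intergenic_rpkm, quantile = 0.95,
                                          library_id = "lib1") {
  if (length(intergenic_rpkm) == 0) stop("no intergenic RPKM values")
  stopifnot(quantile >= 0, quantile <= 1)
  thr <- as.numeric(stats::quantile(intergenic_rpkm, quantile, type = 1,
                                    names = FALSE))
  structure(list(library_id = library_id, threshold = thr,
                 quantile = quantile, n_regions = length(intergenic_rpkm)),
            class = "background_threshold")
}

#' @export
print.background_threshold <- function(x, ...) {
  cat(sprintf(
    "Background threshold for '%s': RPKM %.4g (quantile %.2f of %d intergenic regions)\n",
    x$library_id, x$threshold, x$quantile, x$n_regions))
  invisible(x)
}

#' Flag expressed genes against per-library background thresholds
#'
#' A gene is flagged expressed in a library iff its RPKM is at or above that
#' library's background threshold. In a pairwise comparison a gene is kept
#' for differential expression if it is flagged in at least one of the two
#' libraries (genes below the threshold in both are discarded).
#'
#' @param rpkm_matrix numeric matrix, genes x libraries (column names =
#'   library ids).
#' @param thresholds named numeric vector or list of `background_threshold`
#'   objects covering every column of `rpkm_matrix`.
#' @return logical matrix of the same shape.
#' @export
filter_expressed <- function(rpkm_matrix, thresholds) {
  if (is.list(thresholds) && all(vapply(thresholds, inherits, TRUE,
                                        "background_threshold")))
    thresholds <- stats::setNames(
      vapply(thresholds, `[[`, 0, "threshold"),
      vapply(thresholds, `[[`, "", "library_id"))
  libs <- colnames(rpkm_matrix)
  if (is.null(libs)) libs <- names(thresholds)[seq_len(ncol(rpkm_matrix))]
  missing <- setdiff(libs, names(thresholds))
  if (length(missing))
    stop("no background threshold for library: ",
         paste(missing, collapse = ", "))
  out <- sweep(rpkm_matrix, 2, thresholds[libs], ">=")
  dimnames(out) <- dimnames(rpkm_matrix)
  out
}

#' Relative expression ratio by the 2^-ddCT method
#'
#' @param ct_target_test,ct_endogenous_test cycle thresholds of the target
#'   and endogenous-control gene in the test sample.
#' @param ct_target_control,ct_endogenous_control the same in the control
#'   sample.
#' @return `2^-((ct_target_test - ct_endogenous_test) -
#'   (ct_target_control - ct_endogenous_control))`.
#' @examples
#' ddct_fold_change(20, 18, 24, 20) # 4
#' @export
ddct_fold_change <- function(ct_target_test, ct_endogenous_test,
                             ct_target_control, ct_endogenous_control) {
  stopifnot(is.finite(ct_target_test), is.finite(ct_endogenous_test),
            is.finite(ct_target_control), is.finite(ct_endogenous_control))
  ddct <- (ct_target_test - ct_endogenous_test) -
    (ct_target_control - ct_endogenous_control)
  2^(-ddct)
}
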
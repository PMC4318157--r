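## Differential expression between two libraries (exact conditional binomial
## rate-ratio test) or two groups of libraries (Welch test on log2(RPKM+1)),
## called at the study's criteria: |ratio| >= 2 and p < 0.01.

#' Two-library differential expression
#'
#' For each gene the fold change is computed on library-size-normalised
#' counts (`C1/N1` vs `C2/N2`, with a pseudocount of 1 substituted for zero
#' counts) and the p-value from the exact conditional binomial construction
#' for a rate ratio: conditional on `C1 + C2` total reads, `C1` is
#' `Binomial(C1 + C2, N1/(N1+N2))` under the null of equal rates; the
#' two-sided p-value uses the minimum-likelihood method. A gene is called
#' `up` (higher in library 2) or `down` when `|ratio| >= min_ratio` and
#' `p < alpha`.
#'
#' @param C1,C2 integer count vectors (same genes, same order).
#' @param N1,N2 total aligned reads in each library.
#' @param gene_ids optional gene identifiers.
#' @param alpha p-value cutoff (default 0.01).
#' @param min_ratio fold-change cutoff (default 2).
#' @param expressed1,expressed2 optional logical vectors from
#'   [filter_expressed()]; genes expressed in neither library are excluded
#'   (call `none`, `excluded_by_threshold` TRUE).
#' @param fdr apply Benjamini-Hochberg correction before calling (off by
#'   default; the original criteria use raw p-values).
#' @return data.frame of class `de_result`: `gene_id`, `log2fc`
#'   (library 2 over library 1), `pvalue`, `call` (`up`/`down`/`none`),
#'   `excluded_by_threshold`.
#' @export
de_two_library <- function(C1, N1, C2, N2, gene_ids = NULL, alpha = 0.01,
                           min_ratio = 2, expressed1 = NULL,
                           expressed2 = NULL, fdr = FALSE) {
  if (any(C1 < 0) || any(C2 < 0)) stop("negative counts")
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive")
  n <- length(C1)
  stopifnot(length(C2) == n)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(n))
  excluded <- if (!is.null(expressed1) && !is.null(expressed2))
    !(expressed1 | expressed2) else rep(FALSE, n)

  c1p <- ifelse(C1 == 0, 1, C1)
  c2p <- ifelse(C2 == 0, 1, C2)
  log2fc <- log2((c2p / N2) / (c1p / N1))
  p0 <- N1 / (N1 + N2)
  pvalue <- vapply(seq_len(n), function(i) {
    tot <- C1[i] + C2[i]
    if (tot == 0) return(1)
    stats::binom.test(C1[i], tot, p = p0)$p.value
  }, 0)
  pcall <- if (fdr) stats::p.adjust(pvalue, "BH") else pvalue
  call <- rep("none", n)
  sig <- !excluded & pcall < alpha & abs(log2fc) >= log2(min_ratio)
  call[sig & log2fc > 0] <- "up"
  call[sig & log2fc < 0] <- "down"
  out <- data.frame(gene_id = gene_ids, log2fc = log2fc, pvalue = pvalue,
                    call = call, excluded_by_threshold = excluded,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", class(out))
  out
}

#' Grouped differential expression with libraries as replicates
#'
#' Mirrors the study's between-condition comparison in which the time-point
#' libraries of each fermentation serve as replicates. Fold change is the
#' ratio of group mean RPKM (a pseudocount of 1 RPKM substitutes a zero
#' group mean); the p-value comes from a two-sample unequal-variance (Welch)
#' test on `log2(RPKM + 1)`. Genes expressed (per [filter_expressed()]) in
#' no library of either group are excluded.
#'
#' @param rpkm_a,rpkm_b numeric matrices, genes x libraries (>= 2 columns
#'   each), same genes in the same order.
#' @param alpha,min_ratio calling criteria (default 0.01, 2).
#' @param expressed_a,expressed_b optional logical matrices matching the
#'   RPKM matrices.
#' @return data.frame of class `de_result` (fold change of group B over
#'   group A).
#' @export
de_grouped <- function(rpkm_a, rpkm_b, alpha = 0.01, min_ratio = 2,
                       expressed_a = NULL, expressed_b = NULL) {
  if (ncol(rpkm_a) < 2 || ncol(rpkm_b) < 2)
    stop("each group needs at least 2 libraries")
  n <- nrow(rpkm_a)
  stopifnot(nrow(rpkm_b) == n)
  gene_ids <- rownames(rpkm_a)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(n))
  excluded <- if (!is.null(expressed_a) && !is.null(expressed_b))
    rowSums(expressed_a) + rowSums(expressed_b) == 0 else rep(FALSE, n)
  ma <- rowMeans(rpkm_a); mb <- rowMeans(rpkm_b)
  log2fc <- log2(ifelse(mb == 0, 1, mb) / ifelse(ma == 0, 1, ma))
  la <- log2(rpkm_a + 1); lb <- log2(rpkm_b + 1)
  pvalue <- vapply(seq_len(n), function(i) {
    a <- la[i, ]; b <- lb[i, ]
    if (stats::var(a) + stats::var(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    stats::t.test(a, b)$p.value
  }, 0)
  call <- rep("none", n)
  sig <- !excluded & pvalue < alpha & abs(log2fc) >= log2(min_ratio)
  call[sig & log2fc > 0] <- "up"
  call[sig & log2fc < 0] <- "down"
  out <- data.frame(gene_id = gene_ids, log2fc = log2fc, pvalue = pvalue,
                    call = call, excluded_by_threshold = excluded,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", class(out))
  out
}

#' Summarise differential-expression calls
#'
#' Direction convention follows the study's summary table: `up` = higher in
#' the second library/condition, `down` = higher in the first;
#' `total = up + down` always.
#'
#' @param results a `de_result` data.frame.
#' @return list with `total`, `up`, `down`.
#' @export
tabulate_de <- function(results) {
  up <- sum(results$call == "up")
  down <- sum(results$call == "down")
  list(total = up + down, up = up, down = down)
}

#' @export
print.de_result <- function(x, ...) {
  t <- tabulate_de(x)
  cat(sprintf("DE results: %d genes tested, %d excluded by threshold; %d DE (%d up, %d down)\n",
              nrow(x), sum(x$excluded_by_threshold), t$total, t$up, t$down))
  invisible(x)
}
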
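## In-silico restriction digest, used as the marker-prediction utility for
## genotyping a heterozygous SNP that destroys a recognition site (MboI,
## ^GATC, by default): a cut allele yields two fragments, the uncut allele
## one full-length fragment.

#' Predict restriction fragment lengths
#'
#' Cuts immediately before every occurrence of the recognition site (offset
#' 0, as for MboI's ^GATC; other enzymes via `cut_offset` bases into the
#' site). Sites destroyed by a sequence variant simply do not match and
#' yield no cut. Fragment lengths always sum to the sequence length.
#'
#' @param sequence DNA sequence (character).
#' @param recognition_site recognition sequence (default `"GATC"`).
#' @param cut_offset bases downstream of the site start where the cut falls
#'   (default 0 = immediately before the site).
#' @return integer vector of fragment lengths, 5' to 3'.
#' @examples
#' insilico_digest(paste0(strrep("A", 543), "GATC", strrep("A", 252)))
#' # 543 256
#' @export
insilico_digest <- function(sequence, recognition_site = "GATC",
                            cut_offset = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("empty sequence")
  L <- nchar(sequence)
  hits <- gregexpr(recognition_site, sequence, fixed = TRUE)[[1]]
  cuts <- if (hits[1] == -1) integer(0) else as.integer(hits) + cut_offset
  cuts <- cuts[cuts > 1 & cuts <= L] # a cut at position q falls before base q
  as.integer(diff(c(1L, cuts, L + 1L)))
}
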
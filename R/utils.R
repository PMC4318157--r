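## Internal helpers shared across modules.

#' Exact integer allocation by largest remainder
#'
#' Splits `n` items across categories in proportions `fractions` so that the
#' result sums exactly to `round(sum(fractions) * n)` and each count is within
#' one of `n * fraction`. Used wherever planted compositions must be hit
#' exactly rather than multinomially sampled.
#'
#' @param n total number of items.
#' @param fractions non-negative numeric vector (names preserved); the sum may
#'   be below 1, in which case the remainder is simply not allocated.
#' @return integer vector of counts, same names as `fractions`.
#' @keywords internal
alloc_exact <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0), sum(fractions) <= 1 + 1e-9)
  target <- fractions * n
  base <- floor(target)
  total <- round(sum(target))
  rem <- target - base
  short <- total - sum(base)
  if (short > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Random DNA sequence
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Substitute bases at given positions
#' @keywords internal
subst_bases <- function(seq, pos, bases) {
  if (length(pos) == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v[pos] <- bases
  paste(v, collapse = "")
}

## run `expr` under a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## small deterministic integer hash of a string, < 2^31, for seed derivation
str_seed <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 1999999943
  as.integer(h)
}

## write a TSV with a commented parameter-echo header
write_tsv_report <- function(df, path, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(params)) {
    for (nm in names(params)) {
      writeLines(sprintf("# %s = %s", nm,
                         paste(format(params[[nm]]), collapse = ",")), con)
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
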
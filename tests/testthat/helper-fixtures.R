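# Shared fixtures and independent oracles, all built in code.

# deterministic toy gene table with phased SNPs for allelic tests
toy_gene <- function() {
  list(seq_h1 = paste0(strrep("A", 10), "C", strrep("A", 29), "G",
                       strrep("A", 19)), # 60 bp, SNPs at 11 (C/T) and 41 (G/A)
       snps = data.frame(gene_id = "g1", chrom = "chr01",
                         pos = c(111L, 141L), local_pos = c(11L, 41L),
                         h1 = c("C", "G"), h2 = c("T", "A"),
                         stringsAsFactors = FALSE))
}

# brute-force reference scan: best <=max_mm placement over all features and
# offsets; independent of the seeded C++ matcher
brute_align <- function(read, refs, max_mm = 2) {
  rl <- nchar(read)
  rb <- strsplit(read, "")[[1]]
  best <- max_mm + 1L
  locs <- list()
  for (f in seq_along(refs)) {
    sb <- strsplit(refs[[f]], "")[[1]]
    L <- length(sb)
    if (L < rl) next
    for (s in seq_len(L - rl + 1)) {
      mm <- sum(sb[s:(s + rl - 1)] != rb)
      if (mm > max_mm) next
      if (mm < best) { best <- mm; locs <- list() }
      if (mm == best) locs[[length(locs) + 1]] <- c(f, s)
    }
  }
  if (length(locs) == 0) return(list(status = "unaligned"))
  if (length(locs) > 1) return(list(status = "repeat", mm = best,
                                    n = length(locs)))
  list(status = "unique", feature = locs[[1]][1], pos = locs[[1]][2],
       mm = best)
}

# exhaustive-window LOH oracle: every maximal window of same-haplotype
# monoallelic genes bridged by <= max_gap consecutive uninformative genes
brute_loh <- function(calls, mono_fraction = 0.95, min_genes = 10,
                      max_gap = 2) {
  n <- nrow(calls)
  af <- calls$allele1_fraction
  state <- ifelse(calls$call == "uninformative", 0L,
                  ifelse(!is.na(af) & af >= mono_fraction, 1L,
                         ifelse(!is.na(af) & 1 - af >= mono_fraction, 2L,
                                -1L)))
  valid_tab <- function(d) {
    V <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      if (state[i] != d) next
      gap <- 0L; ok <- TRUE
      for (j in i:n) {
        s <- state[j]
        if (s == d) gap <- 0L
        else if (s == 0L) { gap <- gap + 1L; if (gap > max_gap) ok <- FALSE }
        else ok <- FALSE
        if (!ok) break
        if (s == d) V[i, j] <- TRUE # window must end on a monoallelic gene
      }
    }
    V
  }
  segs <- list()
  for (d in c(1L, 2L)) {
    V <- valid_tab(d)
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!V[i, j]) next
        # maximal: no strictly larger valid window contains it
        ext <- FALSE
        for (i2 in seq_len(i)) for (j2 in j:n) {
          if ((i2 < i || j2 > j) && V[i2, j2]) ext <- TRUE
        }
        if (ext) next
        count <- sum(state[i:j] == d)
        if (count < min_genes) next
        segs[[length(segs) + 1]] <- data.frame(
          start = calls$start[i], end = calls$end[j], gene_count = count,
          dominant_haplotype = d)
      }
    }
  }
  if (length(segs) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      gene_count = integer(0),
                      dominant_haplotype = integer(0)))
  out <- unique(do.call(rbind, segs))
  out[order(out$start), , drop = FALSE]
}

# minimum-likelihood two-sided binomial p-value by full enumeration
brute_binom_p <- function(k, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# random DAE call table for property tests
random_calls <- function(n, seed) {
  set.seed(seed)
  af <- runif(n)
  call <- ifelse(runif(n) < 0.15, "uninformative",
                 ifelse(af >= 2 / 3, "allele1",
                        ifelse(af <= 1 / 3, "allele2", "balanced")))
  af[call == "uninformative"] <- NA
  starts <- cumsum(sample(600:2000, n))
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = "chrT",
             start = starts, end = starts + 500L,
             allele1_fraction = af, call = call, stringsAsFactors = FALSE)
}
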
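# Independent brute-force oracles. Each re-derives its quantity by direct
# enumeration, sharing no code path with the implementation it checks.

# Exhaustive SSR scanner: tests every (start, kmer) pair, counts whole
# repeat units by direct substring comparison, keeps runs that are maximal
# (the position before the run does not continue the period) and whose
# motif has no shorter period.
oracle_scan <- function(seq, min_units) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  period_of <- function(m) {
    L <- nchar(m)
    for (p in seq_len(L)) {
      if (L %% p == 0 && m == strrep(substr(m, 1, p), L / p)) return(p)
    }
    L
  }
  out <- list()
  for (k in 2:6) {
    if (n < 2 * k) next
    for (s in seq_len(n - 2 * k + 1)) {
      motif <- substr(seq, s, s + k - 1)
      if (grepl("N", motif, fixed = TRUE)) next
      if (period_of(motif) < k) next
      # run must start here: previous position must not continue the period
      if (s > 1 && ch[s - 1] != "N" && ch[s - 1] == ch[s - 1 + k]) next
      u <- 1
      while (s + (u + 1) * k - 1 <= n &&
             substr(seq, s + u * k, s + (u + 1) * k - 1) == motif) {
        u <- u + 1
      }
      if (u < min_units[[as.character(k)]]) next
      out[[length(out) + 1]] <- data.frame(
        kmer = k, motif = motif, units = u,
        start = s - 1L, end = s - 1L + u * k, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(kmer = integer(0), motif = character(0),
                      units = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$kmer), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Rarefaction by complete enumeration: mean number of distinct alleles over
# every g-subset of the N allele copies (feasible for N <= 12).
oracle_richness <- function(counts, g) {
  copies <- rep(names(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
}

# Probability that two allele copies drawn without replacement differ,
# by exhaustive enumeration of ordered pairs.
oracle_pair_het <- function(counts) {
  copies <- rep(seq_along(counts), counts)
  N <- length(copies)
  diff_ct <- 0L
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i != j && copies[i] != copies[j]) diff_ct <- diff_ct + 1L
    }
  }
  diff_ct / (N * (N - 1))
}

# random DNA of given length
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# genotype matrix from a plain 2-column matrix of labels
gm_from_matrix <- function(m, locus = "L1", replicate = 1L) {
  genotype_matrix(data.frame(
    individual_id = sprintf("ind%03d", seq_len(nrow(m))),
    locus_id = locus, replicate = replicate,
    allele_a = m[, 1], allele_b = m[, 2], stringsAsFactors = FALSE))
}

default_min_units <- msatkit::msat_config()$min_units
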
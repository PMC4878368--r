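#' Allele counts at a locus
#'
#' @param genotypes two-column matrix of allele labels, one row per complete
#'   genotype (see [locus_genotypes()]).
#' @return named integer vector of allele copy counts, sorted by label;
#'   `sum()` is twice the number of genotypes.
#' @export
allele_counts <- function(genotypes) {
  v <- as.vector(genotypes)
  v <- v[!is.na(v)]
  if (length(v) %% 2 != 0) stop("genotypes must be complete diploid pairs")
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))[order(as.numeric(names(tab)))]
}

#' Observed heterozygosity
#'
#' Fraction of complete genotypes whose two alleles differ; missing calls
#' are excluded from numerator and denominator.
#'
#' @param genotypes two-column matrix of allele labels (rows with any `NA`
#'   are dropped).
#' @return proportion in \[0, 1\].
#' @export
observed_het <- function(genotypes) {
  ok <- stats::complete.cases(genotypes)
  if (!any(ok)) stop("no complete genotypes")
  mean(genotypes[ok, 1] != genotypes[ok, 2])
}

#' Expected heterozygosity (Nei's unbiased estimator)
#'
#' `He = 2n/(2n - 1) * (1 - sum(p_i^2))` with `p_i` the sample allele
#' frequencies and `n` the number of diploid individuals. The small-sample
#' factor makes He the probability that two allele copies drawn *without*
#' replacement differ; set `unbiased = FALSE` for the plain gene-diversity
#' `1 - sum(p_i^2)`.
#'
#' @param counts named allele copy counts (see [allele_counts()]).
#' @param unbiased apply the `2n/(2n-1)` correction (default).
#' @return proportion in \[0, 1\].
#' @export
expected_het <- function(counts, unbiased = TRUE) {
  N <- sum(counts)
  if (N < 2) stop("need at least 2 allele copies")
  p <- counts / N
  he <- 1 - sum(p^2)
  if (unbiased) he <- he * N / (N - 1)
  he
}

# Pearson chi-square over all genotype classes, observed vs HWE-expected
# (n p_i^2 homozygotes, 2 n p_i p_j heterozygotes), on integer-coded pairs
hwe_chisq_stat <- function(ca, cb, expected) {
  K <- nrow(expected)
  idx <- (pmin(ca, cb) - 1L) * K + pmax(ca, cb)
  obs <- tabulate(idx, nbins = K * K)
  use <- expected > 0
  sum((obs[use] - expected[use])^2 / expected[use])
}

hwe_expected_counts <- function(counts, n) {
  K <- length(counts)
  p <- counts / sum(counts)
  E <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in i:K) {
      E[i, j] <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
    }
  }
  t(E)  # row-major index (i-1)*K + j with i <= j
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' The statistic is the Pearson chi-square over all genotype classes
#' (observed vs HWE-expected counts). Its null distribution is obtained by
#' `B` random re-pairings of the pooled allele vector: shuffle the `2n`
#' allele copies and pair consecutive copies, which holds the allele counts
#' fixed while randomizing the genotypes. The p-value is
#' `(1 + #{permuted stat >= observed}) / (B + 1)`. A monomorphic locus
#' returns p = 1 by convention.
#'
#' @param genotypes two-column matrix of allele labels; rows with `NA`
#'   dropped.
#' @param B number of permutations (default 1999).
#' @param seed integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @return list with `p_value`, `statistic`, `B`.
#' @export
hwe_test_mc <- function(genotypes, B = 1999L, seed = NULL) {
  ok <- stats::complete.cases(genotypes)
  genotypes <- genotypes[ok, , drop = FALSE]
  n <- nrow(genotypes)
  if (n == 0) stop("no complete genotypes")
  lev <- sort(unique(as.vector(genotypes)))
  if (length(lev) < 2) {
    return(list(p_value = 1, statistic = 0, B = as.integer(B)))
  }
  ca <- match(genotypes[, 1], lev)
  cb <- match(genotypes[, 2], lev)
  counts <- tabulate(c(ca, cb), nbins = length(lev))
  E <- hwe_expected_counts(counts, n)
  obs_stat <- hwe_chisq_stat(ca, cb, E)
  pool <- c(ca, cb)
  i1 <- seq(1L, 2L * n, by = 2L)
  i2 <- i1 + 1L
  with_seed(seed, {
    ge <- vapply(seq_len(B), function(b) {
      perm <- sample(pool)
      hwe_chisq_stat(perm[i1], perm[i2], E) >= obs_stat - 1e-12
    }, logical(1))
    list(p_value = (1 + sum(ge)) / (B + 1), statistic = obs_stat,
         B = as.integer(B))
  })
}

#' Adjust p-values for multiple comparisons
#'
#' Step-down Holm (default) or step-up Benjamini-Hochberg, order-preserving
#' with the input, clipped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param method `"holm"` or `"bh"`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(pvals, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = c(holm = "holm", bh = "BH")[method])
}

#' Null-allele frequency (Brookfield estimator 1)
#'
#' `r = (He - Ho) / (1 + He)`, truncated at zero: a heterozygote deficit is
#' attributed to a non-amplifying allele whose homozygotes are read as
#' missing and whose heterozygotes are read as visible homozygotes. When
#' observed heterozygosity meets or exceeds expectation the estimate is 0.
#'
#' @param obs_het,exp_het observed and expected heterozygosity in \[0, 1\].
#' @return estimated null-allele frequency in \[0, 1).
#' @export
null_allele_freq <- function(obs_het, exp_het) {
  stopifnot(obs_het >= 0, obs_het <= 1, exp_het >= 0, exp_het <= 1)
  pmax(0, (exp_het - obs_het) / (1 + exp_het))
}

#' Rarefaction allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` allele
#' copies drawn without replacement from the `N` observed copies:
#' `sum_i [1 - C(N - N_i, g) / C(N, g)]`, computed with log-binomials for
#' stability. `g = N` returns the raw allele count; `g = 1` returns 1.
#'
#' @param counts named allele copy counts (see [allele_counts()]).
#' @param g standardized subsample size, `1 <= g <= N`.
#' @return expected allele number in `[1, length(counts)]`.
#' @export
allelic_richness <- function(counts, g) {
  N <- sum(counts)
  if (g < 1 || g > N) stop("g must be in [1, N]; N = ", N)
  # lchoose(a, g) is -Inf when a < g, so the term collapses to 1
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Replicate genotyping error rate
#'
#' Fraction of individuals whose two replicate genotypes differ as
#' unordered allele pairs, among individuals with a complete genotype in
#' both replicates. The unit is the genotype; `per_allele = TRUE` instead
#' counts mismatched alleles out of `2 x` compared genotypes.
#'
#' @param rep1,rep2 two-column matrices of allele labels with individual
#'   ids as rownames (see [locus_genotypes()]).
#' @param per_allele count allele mismatches rather than genotype
#'   mismatches.
#' @return proportion in \[0, 1\].
#' @export
genotyping_error_rate <- function(rep1, rep2, per_allele = FALSE) {
  common <- intersect(rownames(rep1)[stats::complete.cases(rep1)],
                      rownames(rep2)[stats::complete.cases(rep2)])
  if (length(common) == 0) stop("no individuals complete in both replicates")
  a <- rep1[common, , drop = FALSE]
  b <- rep2[common, , drop = FALSE]
  sa <- cbind(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))
  sb <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  if (per_allele) {
    mean(c(sa[, 1] != sb[, 1], sa[, 2] != sb[, 2]))
  } else {
    mean(sa[, 1] != sb[, 1] | sa[, 2] != sb[, 2])
  }
}

#' Summarize one locus
#'
#' Assembles every per-locus characterization statistic: sample size, size
#' range, allele count, observed/expected heterozygosity, Monte-Carlo HWE
#' p-value (raw; adjustment happens across loci in [characterize_loci()]),
#' rarefaction allelic richness, Brookfield null-allele frequency and, when
#' a second replicate is supplied, the replicate genotyping error rate.
#'
#' @param genotypes two-column matrix of allele labels (replicate 1).
#' @param replicate optional two-column matrix for the repeat genotyping;
#'   both need individual ids as rownames for the comparison.
#' @param locus_id recorded in the row.
#' @param g rarefaction subsample size (allele copies); defaults to `2n` of
#'   this locus (i.e. no rarefaction).
#' @param B,seed Monte-Carlo settings for the HWE test.
#' @param unbiased_he use Nei's small-sample correction for He.
#' @return one-row data frame with the `locus_summary` columns
#'   (`hwe_p_adj` is `NA` until adjusted).
#' @export
summarize_locus <- function(genotypes, replicate = NULL, locus_id = "locus",
                            g = NULL, B = 1999L, seed = NULL,
                            unbiased_he = TRUE) {
  ok <- stats::complete.cases(genotypes)
  if (!any(ok)) stop("no complete genotypes at ", locus_id)
  gt <- genotypes[ok, , drop = FALSE]
  n <- nrow(gt)
  counts <- allele_counts(gt)
  if (is.null(g)) g <- 2L * n
  ho <- observed_het(gt)
  he <- if (sum(counts > 0) > 1) expected_het(counts, unbiased_he) else 0
  data.frame(
    locus = locus_id,
    n = n,
    range_min = min(as.numeric(names(counts))),
    range_max = max(as.numeric(names(counts))),
    n_alleles = length(counts),
    obs_het = ho,
    exp_het = he,
    hwe_p_raw = hwe_test_mc(gt, B = B, seed = seed)$p_value,
    hwe_p_adj = NA_real_,
    allelic_richness = allelic_richness(counts, g),
    null_freq = null_allele_freq(ho, he),
    error_rate = if (is.null(replicate)) NA_real_ else
      genotyping_error_rate(genotypes, replicate),
    stringsAsFactors = FALSE
  )
}

#' Characterize every locus of a genotype matrix
#'
#' The main entry point of the characterization stage. For each locus it
#' computes the full summary row (see [summarize_locus()]) from the
#' replicate-1 genotypes, uses replicate 2 (when present) for the error
#' rate, and then adjusts the HWE p-values across loci. Rarefaction uses a
#' common subsample size `g` so richness is comparable across loci with
#' unequal sample sizes; the default is twice the smallest per-locus
#' number of complete genotypes.
#'
#' @param x a [genotype_matrix()].
#' @param config an [msat_config()]; supplies the Monte-Carlo permutation
#'   count, adjustment method, rarefaction `g` and master seed (each locus
#'   tests on its own named sub-stream, so locus order never changes a
#'   p-value).
#' @param include_monomorphic_in_adjust include loci with a single allele
#'   (p = 1 by convention) in the multiple-testing adjustment.
#' @return an object of class `locus_summary`: a data frame with one row
#'   per locus and columns `locus`, `n`, `range_min`, `range_max`,
#'   `n_alleles`, `obs_het`, `exp_het`, `hwe_p_raw`, `hwe_p_adj`,
#'   `allelic_richness`, `null_freq`, `error_rate`; allele frequencies per
#'   locus in `attr(, "allele_freqs")`, the `g` used in `attr(, "g")`.
#' @examples
#' sim <- simulate_genotypes(30, c("100" = 0.5, "104" = 0.3, "108" = 0.2),
#'                           seed = 7)
#' fit <- characterize_loci(sim$genotypes, msat_config(hwe_B = 199, seed = 7))
#' fit
#' @export
characterize_loci <- function(x, config = msat_config(),
                              include_monomorphic_in_adjust = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"))
  has_rep2 <- any(x$calls$replicate == 2L)
  per_locus <- lapply(x$loci, function(lc) {
    gt <- locus_genotypes(x, lc, replicate = 1L)
    if (nrow(gt) == 0) return(NULL)
    list(locus = lc, gt = gt,
         rep2 = if (has_rep2) locus_genotypes(x, lc, replicate = 2L))
  })
  per_locus <- Filter(Negate(is.null), per_locus)
  if (!length(per_locus)) stop("no locus has a complete genotype")
  n_min <- min(vapply(per_locus, function(z) nrow(z$gt), 1L))
  g <- if (is.null(config$rarefaction_g)) 2L * n_min else config$rarefaction_g
  rows <- lapply(per_locus, function(z) {
    rep2 <- z$rep2
    if (!is.null(rep2) && nrow(rep2) == 0) rep2 <- NULL
    summarize_locus(z$gt, replicate = rep2, locus_id = z$locus, g = g,
                    B = config$hwe_B,
                    seed = stream_seed(config$seed, paste0("hwe:", z$locus)))
  })
  out <- do.call(rbind, rows)
  adj <- rep(NA_real_, nrow(out))
  in_adj <- if (include_monomorphic_in_adjust) rep(TRUE, nrow(out)) else
    out$n_alleles > 1
  adj[in_adj] <- adjust_pvalues(out$hwe_p_raw[in_adj], config$adjust_method)
  adj[!in_adj] <- 1
  out$hwe_p_adj <- adj
  rownames(out) <- NULL
  freqs <- lapply(per_locus, function(z) {
    cnt <- allele_counts(z$gt)
    cnt / sum(cnt)
  })
  structure(out,
            allele_freqs = stats::setNames(freqs,
                                           vapply(per_locus, `[[`, "",
                                                  "locus")),
            g = g, config = config,
            class = c("locus_summary", "data.frame"))
}

#' @export
print.locus_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Locus characterization: %d loci (rarefaction g = %d)\n\n",
              nrow(x), attr(x, "g")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) &
    !names(df) %in% c("n", "range_min", "range_max", "n_alleles")
  df[num] <- lapply(df[num], function(v) round_half_up(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.locus_summary <- function(object, alpha = 0.05, ...) {
  cat(sprintf("%d loci; alleles per locus %d-%d; Ho %.2f-%.2f; He %.2f-%.2f\n",
              nrow(object), min(object$n_alleles), max(object$n_alleles),
              min(object$obs_het), max(object$obs_het),
              min(object$exp_het), max(object$exp_het)))
  dev <- object$locus[!is.na(object$hwe_p_adj) & object$hwe_p_adj < alpha]
  cat(sprintf("loci out of HWE at adjusted p < %g: %s\n", alpha,
              if (length(dev)) paste(dev, collapse = ", ") else "none"))
  cat(sprintf("null-allele frequency range: %.2f-%.2f\n",
              min(object$null_freq), max(object$null_freq)))
  invisible(object)
}

#' Allele frequencies of a characterized data set
#'
#' @param x a `locus_summary` from [characterize_loci()].
#' @return named list: per locus, a named vector of allele frequencies.
#' @export
allele_freqs <- function(x) {
  stopifnot(inherits(x, "locus_summary"))
  attr(x, "allele_freqs")
}

#' Plot per-locus allele frequency spectra
#'
#' One barplot per locus: each bar an allele, bar height its sample
#' frequency.
#'
#' @param x a `locus_summary`.
#' @param loci subset of loci to draw (default all).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.locus_summary <- function(x, loci = NULL, ...) {
  fr <- allele_freqs(x)
  if (!is.null(loci)) fr <- fr[loci]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(fr)),
                       mar = c(3, 3, 2, 0.5))
  on.exit(graphics::par(old))
  for (lc in names(fr)) {
    graphics::barplot(fr[[lc]], main = lc, las = 2, cex.names = 0.7, ...)
  }
  invisible(x)
}
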
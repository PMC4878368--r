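test_that("observed heterozygosity counts complete genotypes only", {
  expect_equal(observed_het(rbind(c(1, 1), c(1, 2))), 0.5)
  expect_equal(observed_het(rbind(c(1, 1), c(2, 2), c(3, 3))), 0)
  expect_equal(observed_het(rbind(c(1, 2), c(NA, NA), c(1, 1))), 0.5)
  expect_error(observed_het(rbind(c(NA, NA))), "no complete")
})

test_that("expected heterozygosity matches the pair-draw probability", {
  expect_equal(expected_het(c(A = 4)), 0)
  # counts {A:3, B:1}: (4/3) * (1 - 9/16 - 1/16) = 0.5
  expect_equal(expected_het(c(A = 3, B = 1)), 0.5)
  # equals the exhaustive two-copies-without-replacement probability
  set.seed(13)
  for (i in 1:25) {
    counts <- rpois(sample(2:6, 1), 3) + 1L
    names(counts) <- seq_along(counts)
    expect_equal(expected_het(counts), oracle_pair_het(counts),
                 tolerance = 1e-12)
  }
  # uncorrected gene diversity available
  expect_equal(expected_het(c(A = 2, B = 2), unbiased = FALSE), 0.5)
  expect_error(expected_het(c(A = 1)), "at least 2")
})

test_that("the Monte-Carlo HWE test behaves at its extremes", {
  # monomorphic: p = 1 by convention
  expect_equal(hwe_test_mc(cbind(rep(1, 20), rep(1, 20)))$p_value, 1)
  # 20 individuals, two alleles at 0.5, every individual homozygous:
  # an extreme heterozygote deficit must be strongly rejected
  deficit <- cbind(c(rep(100, 10), rep(104, 10)),
                   c(rep(100, 10), rep(104, 10)))
  expect_lte(hwe_test_mc(deficit, B = 1999, seed = 3)$p_value, 0.01)
  # p honours its permutation bounds
  p <- hwe_test_mc(deficit, B = 99, seed = 3)$p_value
  expect_gte(p, 1 / 100)
  expect_lte(p, 1)
})

test_that("HWE p-values are bit-reproducible under a fixed seed", {
  set.seed(14)
  g <- cbind(sample(c(100, 104, 108), 30, replace = TRUE),
             sample(c(100, 104, 108), 30, replace = TRUE))
  p1 <- hwe_test_mc(g, B = 499, seed = 77)$p_value
  p2 <- hwe_test_mc(g, B = 499, seed = 77)$p_value
  expect_identical(p1, p2)
  # and the observed statistic is the plain Pearson chi-square
  res <- hwe_test_mc(g, B = 9, seed = 1)
  lev <- sort(unique(as.vector(g)))
  n <- nrow(g)
  p_hat <- table(factor(as.vector(g), levels = lev)) / (2 * n)
  classes <- apply(g, 1, function(r) paste(sort(r), collapse = "/"))
  all_cls <- outer(lev, lev, function(a, b) paste(a, b, sep = "/"))
  keep <- which(lower.tri(all_cls, diag = TRUE), arr.ind = TRUE)
  obs <- exp_ct <- numeric(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    a <- lev[keep[i, 2]]; b <- lev[keep[i, 1]]
    obs[i] <- sum(classes == paste(sort(c(a, b)), collapse = "/"))
    exp_ct[i] <- if (a == b) n * p_hat[[as.character(a)]]^2 else
      2 * n * p_hat[[as.character(a)]] * p_hat[[as.character(b)]]
  }
  expect_equal(res$statistic, sum((obs - exp_ct)^2 / exp_ct))
})

test_that("p-value adjustment reproduces the hand-worked procedures", {
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Brookfield null-allele estimates match published rows", {
  expect_equal(round(null_allele_freq(0.56, 0.82), 2), 0.14)
  expect_equal(null_allele_freq(0.57, 0.52), 0)
  expect_equal(round(null_allele_freq(0.2, 0.78), 2), 0.33)
  # zero exactly when Ho >= He, always in [0, 1)
  set.seed(15)
  ho <- runif(200); he <- runif(200)
  r <- null_allele_freq(ho, he)
  expect_true(all(r >= 0 & r < 1))
  expect_equal(r == 0, ho >= he)
})

test_that("rarefaction richness matches identities and enumeration", {
  counts <- c("100" = 5L, "104" = 3L, "108" = 2L)
  N <- sum(counts)
  expect_equal(allelic_richness(counts, N), length(counts))
  expect_equal(allelic_richness(counts, 1), 1)
  expect_equal(allelic_richness(c(A = 2, B = 2), 2), 2 - 2 / 6)
  # exhaustive subsample enumeration for N <= 12
  set.seed(16)
  for (i in 1:15) {
    cts <- rpois(sample(2:5, 1), 2) + 1L
    if (sum(cts) > 12) cts <- cts - (cts > 1)
    names(cts) <- seq_along(cts)
    g <- sample(sum(cts), 1)
    expect_equal(allelic_richness(cts, g), oracle_richness(cts, g),
                 tolerance = 1e-10)
  }
  # non-decreasing in g, bounded by the allele count
  rich <- vapply(seq_len(N), function(g) allelic_richness(counts, g), 1)
  expect_true(all(diff(rich) >= -1e-12))
  expect_true(all(rich <= length(counts) + 1e-12))
  expect_error(allelic_richness(counts, 0), "g must be")
  expect_error(allelic_richness(counts, N + 1), "g must be")
})

test_that("rarefaction agrees with an independent community-ecology routine", {
  counts <- c(a = 9L, b = 5L, c = 4L, d = 1L, e = 1L)
  for (g in c(2, 5, 10, 15)) {
    expect_equal(allelic_richness(counts, g),
                 as.numeric(vegan::rarefy(t(as.matrix(counts)), g)),
                 tolerance = 1e-10)
  }
})

test_that("replicate error rates count discordant unordered genotypes", {
  m1 <- cbind(rep(100, 50), rep(104, 50))
  rownames(m1) <- sprintf("i%02d", 1:50)
  expect_equal(genotyping_error_rate(m1, m1), 0)
  # allele order within a genotype does not matter
  m2 <- m1[, 2:1]
  rownames(m2) <- rownames(m1)
  expect_equal(genotyping_error_rate(m1, m2), 0)
  m3 <- m1
  m3[1, 2] <- 100
  expect_equal(genotyping_error_rate(m1, m3), 0.02)
  expect_equal(genotyping_error_rate(m1, m3, per_allele = TRUE), 0.01)
  # individuals missing in either replicate are excluded
  m4 <- m1; m4[2, ] <- NA
  expect_equal(genotyping_error_rate(m1, m4), 1 / 49 * 0)
  expect_error(genotyping_error_rate(m1, m1[0, , drop = FALSE]),
               "no individuals")
})

test_that("a monomorphic locus summarizes to its conventional values", {
  m <- cbind(rep(250, 10), rep(250, 10))
  s <- summarize_locus(m, locus_id = "mono", seed = 1)
  expect_equal(s$n_alleles, 1L)
  expect_equal(s$obs_het, 0)
  expect_equal(s$exp_het, 0)
  expect_equal(s$hwe_p_raw, 1)
  expect_equal(s$null_freq, 0)
  expect_equal(s$range_min, 250)
  expect_equal(s$range_max, 250)
})

test_that("characterize_loci assembles, rarefies and adjusts across loci", {
  freqs <- setNames(rep(0.2, 5), as.character(seq(100, 116, 4)))
  sims <- lapply(1:3, function(i)
    simulate_genotypes(20 + 5 * i, freqs, seed = 100 + i,
                       locus_id = paste0("L", i))$genotypes)
  calls <- do.call(rbind, lapply(sims, function(g) g$calls))
  g <- genotype_matrix(calls[names(calls) != "valid"])
  fit <- characterize_loci(g, msat_config(hwe_B = 199, seed = 5))
  expect_s3_class(fit, "locus_summary")
  expect_equal(nrow(fit), 3)
  # default g is twice the smallest per-locus n
  expect_equal(attr(fit, "g"), 2L * min(fit$n))
  expect_true(all(fit$allelic_richness <= fit$n_alleles + 1e-12))
  expect_equal(fit$hwe_p_adj,
               adjust_pvalues(fit$hwe_p_raw, "holm"))
  expect_true(all(is.na(fit$error_rate)))  # no replicate genotyping
  # allele frequencies accessor sums to one per locus
  fr <- allele_freqs(fit)
  expect_equal(unname(vapply(fr, sum, 1)), rep(1, 3))
})

test_that("per-locus HWE seeds do not depend on locus order", {
  freqs <- setNames(rep(0.25, 4), as.character(seq(100, 112, 4)))
  g1 <- simulate_genotypes(25, freqs, seed = 31, locus_id = "A")$genotypes
  g2 <- simulate_genotypes(25, freqs, seed = 32, locus_id = "B")$genotypes
  ab <- genotype_matrix(rbind(g1$calls, g2$calls)[1:5])
  ba <- genotype_matrix(rbind(g2$calls, g1$calls)[1:5])
  cfg <- msat_config(hwe_B = 199, seed = 9)
  fa <- characterize_loci(ab, cfg)
  fb <- characterize_loci(ba, cfg)
  expect_equal(fa$hwe_p_raw[fa$locus == "A"],
               fb$hwe_p_raw[fb$locus == "A"])
  expect_equal(fa$hwe_p_raw[fa$locus == "B"],
               fb$hwe_p_raw[fb$locus == "B"])
})

test_that("replicate genotyping feeds the error-rate column", {
  freqs <- setNames(rep(0.25, 4), as.character(seq(100, 112, 4)))
  sim <- simulate_genotypes(60, freqs, miscall_rate = 0.1, seed = 41)
  fit <- characterize_loci(sim$genotypes, msat_config(hwe_B = 99, seed = 2))
  expect_false(is.na(fit$error_rate))
  expect_gte(fit$error_rate, 0)
})
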
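test_that("read simulation is seed-deterministic and collision-free", {
  a <- simulate_reads(25, 100, seed = 51)
  b <- simulate_reads(25, 100, seed = 51)
  expect_identical(a$reads, b$reads)
  # background guarantee: nothing to discover, nothing to count
  expect_equal(nrow(scan_reads(a$reads)), 0)
  c2 <- simulate_reads(25, 100, seed = 52)
  expect_false(identical(a$reads$sequence, c2$reads$sequence))
})

test_that("planted repeats are recovered completely at exact coordinates", {
  planted <- data.frame(motif = c("AC", "AATC"), units = c(9L, 5L),
                        copies = c(5L, 3L))
  sim <- simulate_reads(40, 120, planted = planted, seed = 53)
  hits <- scan_reads(sim$reads)
  expect_equal(nrow(hits), 8)
  truth <- sim$truth$ssr
  truth <- truth[order(truth$read_id, truth$start), ]
  hits <- hits[order(hits$read_id, hits$start), ]
  expect_equal(hits$read_id, truth$read_id)
  expect_equal(hits$start, truth$start)
  expect_equal(hits$units, truth$units)
  expect_equal(hits$canonical_motif, truth$canonical_motif)
  # and the summary equals the planted composition
  sm <- summarize_repeats(hits)
  expect_equal(sm$count[sm$canonical_motif == "AC"], 5)
  expect_equal(sm$count[sm$kmer == 4], 3)
})

test_that("planted primer sites are counted exactly, both orientations", {
  ps <- data.frame(locus_id = c("L1", "L2"),
                   primer = c("ACGTTGCAACGGAT", "TTGACCGGTTAACC"),
                   copies = c(3L, 4L), stringsAsFactors = FALSE)
  sim <- simulate_reads(30, 90, primer_sites = ps, seed = 54)
  expect_equal(count_primer_occurrences(ps$primer[1], sim$reads), 3L)
  expect_equal(count_primer_occurrences(ps$primer[2], sim$reads), 4L)
  # truth records reverse-complement insertions
  expect_true(any(sim$truth$primer$revcomp))
  expect_error(simulate_reads(2, 50, primer_sites = ps, seed = 1),
               "more planted copies")
  expect_error(simulate_reads(10, 10,
                              planted = data.frame(motif = "AC", units = 9,
                                                   copies = 1), seed = 1),
               "longer than read_len")
})

test_that("genotype simulation obeys its degenerate and limiting cases", {
  freqs <- setNames(c(0.5, 0.3, 0.2), c("100", "104", "108"))
  # null_freq 1: everything missing
  allnull <- simulate_genotypes(20, freqs, null_freq = 1, seed = 61)
  expect_true(all(is.na(allnull$genotypes$calls$allele_a)))
  expect_error(simulate_genotypes(5, c("100" = 0.6, "104" = 0.3)),
               "sum to 1")
  # determinism
  s1 <- simulate_genotypes(15, freqs, null_freq = 0.2, seed = 62)
  s2 <- simulate_genotypes(15, freqs, null_freq = 0.2, seed = 62)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  # truth completeness: every emitted call has a truth record
  expect_equal(s1$truth$genotypes$individual_id,
               s1$genotypes$calls$individual_id)
  # without nulls the observed calls equal the true draws
  s0 <- simulate_genotypes(50, freqs, seed = 63)
  tru <- s0$truth$genotypes
  expect_equal(s0$genotypes$calls$allele_a, pmin(tru$allele_a, tru$allele_b))
  expect_equal(s0$genotypes$calls$allele_b, pmax(tru$allele_a, tru$allele_b))
})

test_that("without nulls, observed heterozygosity matches HWE expectation", {
  freqs <- setNames(rep(0.2, 5), as.character(seq(100, 116, 4)))
  true_het <- 1 - sum(freqs^2)
  sim <- simulate_genotypes(1000, freqs, seed = 64)
  ho <- observed_het(locus_genotypes(sim$genotypes, "simlocus"))
  se <- sqrt(true_het * (1 - true_het) / 1000)
  expect_lt(abs(ho - true_het), 3 * se)
})

test_that("null alleles convert heterozygotes to homozygotes, not noise", {
  freqs <- setNames(rep(0.25, 4), as.character(seq(100, 112, 4)))
  sim <- simulate_genotypes(400, freqs, null_freq = 0.3, seed = 65)
  tru <- sim$truth$genotypes
  obs <- sim$genotypes$calls
  # null/null is missing
  bothnull <- is.na(tru$allele_a) & is.na(tru$allele_b)
  expect_true(all(is.na(obs$allele_a[bothnull])))
  # null/visible shows the visible allele twice
  halfnull <- xor(is.na(tru$allele_a), is.na(tru$allele_b))
  vis <- ifelse(is.na(tru$allele_a), tru$allele_b, tru$allele_a)[halfnull]
  expect_equal(obs$allele_a[halfnull], vis)
  expect_equal(obs$allele_b[halfnull], vis)
})

test_that("replicate miscalls are recovered by the error-rate estimator", {
  freqs <- setNames(rep(0.25, 4), as.character(seq(100, 112, 4)))
  sim <- simulate_genotypes(500, freqs, miscall_rate = 0.05, seed = 66)
  r1 <- locus_genotypes(sim$genotypes, "simlocus", replicate = 1L)
  r2 <- locus_genotypes(sim$genotypes, "simlocus", replicate = 2L)
  er <- genotyping_error_rate(r1, r2)
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(er - 0.05), 3 * se)
})

test_that("peak simulation jitters labels and collapses homozygotes", {
  freqs <- setNames(c(0.5, 0.5), c("100", "104"))
  sim <- simulate_genotypes(30, freqs, seed = 71)
  p0 <- simulate_peaks(sim$genotypes, motif_len = 4, jitter = 0, seed = 71)
  cc <- sim$genotypes$calls
  hom <- cc$allele_a == cc$allele_b
  expect_equal(p0$size_a, as.numeric(cc$allele_a))
  expect_true(all(is.na(p0$size_b[hom])))
  expect_equal(p0$size_b[!hom], as.numeric(cc$allele_b[!hom]))
  p1 <- simulate_peaks(sim$genotypes, motif_len = 4, jitter = 0.8, seed = 72)
  expect_true(all(abs(p1$size_a - cc$allele_a) < 0.8))
  expect_error(simulate_peaks(sim$genotypes, motif_len = 4, jitter = 2),
               "jitter")
})

test_that("a dense ladder under near-half-unit jitter is flagged ambiguous", {
  # alleles every repeat unit, jitter 0.45 units: neighbouring clusters
  # bridge into a smear the binning rules must refuse
  freqs <- setNames(rep(0.125, 8), as.character(seq(100, 114, 2)))
  sim <- simulate_genotypes(120, freqs, seed = 73)
  peaks <- simulate_peaks(sim$genotypes, motif_len = 2, jitter = 0.9,
                          seed = 73)
  bm <- bin_all_loci(peaks, motif_len = 2)
  expect_true(bm$simlocus$ambiguous)
})
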
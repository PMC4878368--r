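#' Simulate a read pool with planted SSRs and primer sites
#'
#' Emits reads whose background is i.i.d. uniform ACGT, with each requested
#' repeat and primer site planted in exactly `copies` reads at recorded
#' positions. Background sequence (including the flanks of planted
#' features) is rejection-sampled so that no read accidentally contains a
#' plantable primer or a repeat passing `min_units` beyond what was
#' planted, making downstream count assertions exact rather than
#' probabilistic. Half the planted primer copies (rounded down) are
#' inserted as reverse complements.
#'
#' @param n_reads total number of reads (must cover all planted copies).
#' @param read_len read length in bp.
#' @param planted data frame with columns `motif`, `units`, `copies`:
#'   each row plants `(motif)x(units)` in `copies` distinct reads.
#' @param primer_sites data frame with columns `locus_id`, `primer`,
#'   `copies`.
#' @param seed integer master seed; the read stream is derived from it.
#' @param min_units per-kmer thresholds the background must stay below.
#' @return list: `reads` (data frame as from [read_fastq()]) and `truth`
#'   (list with `ssr` and `primer` data frames recording every planted
#'   feature, plus the seed).
#' @export
simulate_reads <- function(n_reads, read_len, planted = NULL,
                           primer_sites = NULL, seed = 1L,
                           min_units = msat_config()$min_units) {
  n_feat <- sum(planted$copies, primer_sites$copies)
  if (n_feat > n_reads) stop("more planted copies than reads")
  feat_len <- c(
    if (!is.null(planted)) nchar(planted$motif) * planted$units,
    if (!is.null(primer_sites)) nchar(primer_sites$primer)
  )
  if (any(feat_len > read_len)) stop("planted feature longer than read_len")
  primers <- if (is.null(primer_sites)) character(0) else
    toupper(primer_sites$primer)

  clean <- function(s) {
    # no unplanned SSR call and no unplanned primer site, either strand
    if (nrow(scan_read(s, min_units))) return(FALSE)
    for (p in c(primers, revcomp(primers))) {
      if (grepl(p, s, fixed = TRUE)) return(FALSE)
    }
    TRUE
  }
  rand_bases <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }
  clean_read <- function() {
    repeat {
      s <- rand_bases(read_len)
      if (clean(s)) return(s)
    }
  }

  with_seed(stream_seed(seed, "reads"), {
    seqs <- vapply(seq_len(n_reads), function(i) clean_read(), "")
    ids <- sprintf("simread%05d", seq_len(n_reads))
    slot <- sample(n_reads, n_feat)  # which reads carry a feature
    truth_ssr <- list(); truth_primer <- list(); si <- 1L

    plant <- function(read_idx, insert) {
      # overwrite at a random offset, then re-randomize flanks until the
      # whole read is clean apart from the planted feature
      L <- nchar(insert)
      repeat {
        off <- sample(read_len - L + 1L, 1L)
        left <- if (off > 1) rand_bases(off - 1L) else ""
        right <- if (off + L - 1L < read_len)
          rand_bases(read_len - off - L + 1L) else ""
        s <- paste0(left, insert, right)
        if (ok_planted(s, insert, off)) {
          return(list(seq = s, start = off - 1L))  # 0-based
        }
      }
    }
    ok_planted <- function(s, insert, off) {
      hits <- scan_read(s, min_units)
      exp_hits <- scan_read(insert, min_units)
      if (nrow(exp_hits)) {
        # planted repeat: exactly that hit, shifted, nothing else
        exp_hits$start <- exp_hits$start + off - 1L
        exp_hits$end <- exp_hits$end + off - 1L
        if (!identical(hits[c("kmer", "motif", "units", "start", "end")],
                       exp_hits[c("kmer", "motif", "units", "start",
                                  "end")])) return(FALSE)
      } else if (nrow(hits)) return(FALSE)
      for (p in c(primers, revcomp(primers))) {
        want <- if (p == insert) 1L else 0L
        m <- gregexpr(p, s, fixed = TRUE)[[1]]
        cnt <- if (m[1] == -1L) 0L else length(m)
        if (cnt != want) return(FALSE)
      }
      TRUE
    }

    if (!is.null(planted)) {
      for (r in seq_len(nrow(planted))) {
        for (cp in seq_len(planted$copies[r])) {
          idx <- slot[si]; si <- si + 1L
          ins <- strrep(toupper(planted$motif[r]), planted$units[r])
          pl <- plant(idx, ins)
          seqs[idx] <- pl$seq
          truth_ssr[[length(truth_ssr) + 1L]] <- data.frame(
            read_id = ids[idx], motif = toupper(planted$motif[r]),
            canonical_motif = canonical_motif(planted$motif[r]),
            units = planted$units[r], start = pl$start,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!is.null(primer_sites)) {
      for (r in seq_len(nrow(primer_sites))) {
        for (cp in seq_len(primer_sites$copies[r])) {
          idx <- slot[si]; si <- si + 1L
          p <- toupper(primer_sites$primer[r])
          ins <- if (cp %% 2 == 0) revcomp(p) else p
          pl <- plant(idx, ins)
          seqs[idx] <- pl$seq
          truth_primer[[length(truth_primer) + 1L]] <- data.frame(
            read_id = ids[idx], locus_id = primer_sites$locus_id[r],
            primer = p, revcomp = cp %% 2 == 0, start = pl$start,
            stringsAsFactors = FALSE)
        }
      }
    }
    reads <- data.frame(read_id = ids, sequence = seqs,
                        quality = strrep("I", read_len),
                        stringsAsFactors = FALSE)
    truth <- list(
      ssr = if (length(truth_ssr)) do.call(rbind, truth_ssr) else NULL,
      primer = if (length(truth_primer)) do.call(rbind, truth_primer) else
        NULL,
      seed = seed)
    list(reads = reads, truth = truth)
  })
}

#' Simulate diploid genotype matrices under HWE with null alleles
#'
#' Each individual's genotype is two independent allele copies drawn from
#' the full allele distribution: visible alleles carry `(1 - null_freq)`
#' of the mass (scaled from `allele_freqs`), a non-amplifying null allele
#' carries `null_freq`. A null/null draw is recorded as missing; a
#' null/visible draw appears as a homozygote for the visible allele — the
#' dropout mechanism that makes null alleles inflate homozygosity.
#' Additional missingness is applied at `missing_rate`. When
#' `miscall_rate > 0` a second replicate is emitted in which each observed
#' genotype is, with that probability, altered (one allele replaced by a
#' different visible allele), so the replicate discordance rate estimates
#' `miscall_rate`.
#'
#' @param n_ind number of individuals.
#' @param allele_freqs named numeric vector: visible allele label (integer
#'   bp, as character) to frequency; must sum to 1.
#' @param null_freq frequency of the null allele in \[0, 1\].
#' @param miscall_rate per-genotype miscall probability for the replicate.
#' @param missing_rate additional independent missingness per call.
#' @param seed master seed (genotype and replicate streams are derived
#'   from it).
#' @param locus_id locus name in the output.
#' @return list: `genotypes` (a [genotype_matrix()] with replicate 2 rows
#'   when `miscall_rate > 0`) and `truth` (true genotypes before dropout,
#'   the parameters, and the seed).
#' @export
simulate_genotypes <- function(n_ind, allele_freqs, null_freq = 0,
                               miscall_rate = 0, missing_rate = 0,
                               seed = 1L, locus_id = "simlocus") {
  if (abs(sum(allele_freqs) - 1) > 1e-9) {
    stop("allele_freqs must sum to 1")
  }
  if (null_freq < 0 || null_freq > 1) stop("null_freq must be in [0, 1]")
  labels <- as.integer(names(allele_freqs))
  if (anyNA(labels)) stop("allele labels must be integer sizes")
  full_p <- c(allele_freqs * (1 - null_freq), null = null_freq)
  full_lab <- c(labels, NA_integer_)  # NA codes the null allele
  ids <- sprintf("ind%04d", seq_len(n_ind))

  with_seed(stream_seed(seed, "genotypes"), {
    a1 <- full_lab[sample.int(length(full_p), n_ind, replace = TRUE,
                              prob = full_p)]
    a2 <- full_lab[sample.int(length(full_p), n_ind, replace = TRUE,
                              prob = full_p)]
    obs_a <- a1; obs_b <- a2
    # null/visible presents as visible homozygote; null/null as missing
    drop1 <- is.na(a1) & !is.na(a2)
    drop2 <- is.na(a2) & !is.na(a1)
    obs_a[drop1] <- a2[drop1]
    obs_b[drop2] <- a1[drop2]
    both_null <- is.na(a1) & is.na(a2)
    obs_a[both_null] <- NA; obs_b[both_null] <- NA
    if (missing_rate > 0) {
      gone <- stats::runif(n_ind) < missing_rate
      obs_a[gone] <- NA; obs_b[gone] <- NA
    }
    calls <- data.frame(individual_id = ids, locus_id = locus_id,
                        replicate = 1L, allele_a = obs_a, allele_b = obs_b,
                        stringsAsFactors = FALSE)
    truth <- list(
      genotypes = data.frame(individual_id = ids, allele_a = a1,
                             allele_b = a2, stringsAsFactors = FALSE),
      allele_freqs = allele_freqs, null_freq = null_freq,
      miscall_rate = miscall_rate, missing_rate = missing_rate, seed = seed)

    if (miscall_rate > 0) {
      rep2 <- with_seed(stream_seed(seed, "replicate"), {
        ra <- obs_a; rb <- obs_b
        flip <- stats::runif(n_ind) < miscall_rate & !is.na(obs_a)
        for (i in which(flip)) {
          which_allele <- sample(2L, 1L)
          cur <- if (which_allele == 1L) ra[i] else rb[i]
          alt <- labels[labels != cur]
          if (length(alt) == 0) next  # single visible allele: cannot differ
          newv <- if (length(alt) == 1) alt else sample(alt, 1L)
          if (which_allele == 1L) ra[i] <- newv else rb[i] <- newv
        }
        data.frame(individual_id = ids, locus_id = locus_id,
                   replicate = 2L, allele_a = ra, allele_b = rb,
                   stringsAsFactors = FALSE)
      })
      calls <- rbind(calls, rep2)
    }
    list(genotypes = genotype_matrix(calls), truth = truth)
  })
}

#' Simulate raw peak calls from binned genotypes
#'
#' Each allele label is emitted as `label + uniform(-jitter, +jitter)`;
#' homozygotes emit a single peak (empty `size_b`), as a capillary trace
#' would show.
#'
#' @param genotypes a [genotype_matrix()].
#' @param jitter half-width of the uniform size noise in bp; must be below
#'   half a repeat unit for bins to stay separable.
#' @param motif_len repeat unit length (used only to validate `jitter`).
#' @param seed master seed (peak stream derived from it).
#' @return a peak-call data frame (columns as [read_peak_calls()]).
#' @export
simulate_peaks <- function(genotypes, motif_len, jitter, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (jitter >= motif_len / 2) stop("jitter must be < motif_len / 2")
  cc <- genotypes$calls
  with_seed(stream_seed(seed, "peaks"), {
    size_a <- cc$allele_a + stats::runif(nrow(cc), -jitter, jitter)
    size_b <- cc$allele_b + stats::runif(nrow(cc), -jitter, jitter)
    hom <- !is.na(cc$allele_a) & !is.na(cc$allele_b) &
      cc$allele_a == cc$allele_b
    size_b[hom] <- NA
    data.frame(individual_id = cc$individual_id, locus_id = cc$locus_id,
               replicate = cc$replicate, size_a = size_a, size_b = size_b,
               stringsAsFactors = FALSE)
  })
}
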
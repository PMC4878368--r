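#' Bin raw fragment sizes into discrete allele bins
#'
#' Algorithmic replacement for visual histogram binning of capillary peak
#' calls. Sizes are sorted and single-linkage clustered: a new bin starts
#' whenever the gap to the previous size exceeds `gap_factor * motif_len`.
#' Each bin is labelled by the round-half-up of its median size (integer
#' bp). Because alleles of a clean locus differ by whole repeat units, a
#' locus is flagged ambiguous when its bins do not look like a repeat
#' ladder; the ambiguity score is
#'
#'   (# adjacent bin pairs whose label spacing is not a positive whole
#'    multiple of motif_len  +  # bins whose internal spread exceeds
#'    motif_len - 1) / # bins
#'
#' and the locus is ambiguous when the score exceeds `ambiguity_threshold`.
#'
#' @param sizes numeric vector of raw fragment sizes (bp, may be
#'   fractional), length >= 1.
#' @param motif_len repeat unit length of the locus (2-6).
#' @param gap_factor cluster-break multiplier (default 0.5 repeat units).
#' @param ambiguity_threshold score above which the locus is flagged.
#' @param locus_id recorded in the result.
#' @return an object of class `allele_bins`: list with `locus_id`, `bins`
#'   (data frame `label`, `lower`, `upper`, `n`), `ambiguous`,
#'   `ambiguity_score`.
#' @export
bin_alleles <- function(sizes, motif_len, gap_factor = 0.5,
                        ambiguity_threshold = 0.25, locus_id = "locus") {
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) == 0) stop("no sizes to bin for ", locus_id)
  if (motif_len < 2 || motif_len > 6) stop("motif_len must be 2-6")
  s <- sort(sizes)
  brk <- which(diff(s) > gap_factor * motif_len)
  grp <- rep(seq_len(length(brk) + 1L), diff(c(0L, brk, length(s))))
  bins <- do.call(rbind, lapply(split(s, grp), function(v) {
    data.frame(label = as.integer(round_half_up(stats::median(v))),
               lower = min(v), upper = max(v), n = length(v))
  }))
  rownames(bins) <- NULL
  spread_bad <- sum(bins$upper - bins$lower > motif_len - 1)
  spacing_bad <- if (nrow(bins) > 1) {
    d <- diff(bins$label)
    sum(d <= 0 | d %% motif_len != 0)
  } else 0L
  score <- (spacing_bad + spread_bad) / nrow(bins)
  structure(list(locus_id = locus_id, bins = bins,
                 ambiguous = score > ambiguity_threshold,
                 ambiguity_score = score),
            class = "allele_bins")
}

#' @export
print.allele_bins <- function(x, ...) {
  cat(sprintf("allele bins for %s: %d bin(s), ambiguity score %.2f%s\n",
              x$locus_id, nrow(x$bins), x$ambiguity_score,
              if (x$ambiguous) " [AMBIGUOUS]" else ""))
  print(x$bins, ...)
  invisible(x)
}

#' Bin every locus of a peak-call table
#'
#' @param peaks peak-call data frame (see [read_peak_calls()]).
#' @param motif_len named vector mapping locus id to repeat unit length, or
#'   a single value applied to all loci.
#' @param gap_factor,ambiguity_threshold see [bin_alleles()].
#' @return named list of `allele_bins`, one per locus.
#' @export
bin_all_loci <- function(peaks, motif_len, gap_factor = 0.5,
                         ambiguity_threshold = 0.25) {
  loci <- unique(peaks$locus_id)
  ml <- if (length(motif_len) == 1 && is.null(names(motif_len))) {
    stats::setNames(rep(motif_len, length(loci)), loci)
  } else motif_len
  if (!all(loci %in% names(ml))) stop("motif_len missing for some loci")
  res <- lapply(loci, function(lc) {
    pp <- peaks[peaks$locus_id == lc, ]
    bin_alleles(c(pp$size_a, pp$size_b), ml[[lc]], gap_factor,
                ambiguity_threshold, locus_id = lc)
  })
  stats::setNames(res, loci)
}

#' Assign binned genotypes from raw peak calls
#'
#' Maps each peak size to the bin whose `[lower, upper]` interval contains
#' it. A single present peak becomes a homozygote
#' (label duplicated), the standard fragment-analysis convention; note this
#' interacts with null alleles, which also present as single peaks. A size
#' falling outside all bins makes that call missing, with a warning and an
#' out-of-bin rate recorded.
#'
#' @param peaks peak-call data frame (see [read_peak_calls()]).
#' @param bin_maps named list of `allele_bins` (ambiguous loci are dropped
#'   with a warning).
#' @return a [genotype_matrix()]; `attr(, "out_of_bin_rate")` reports the
#'   fraction of peaks that fell outside every bin.
#' @export
assign_genotypes <- function(peaks, bin_maps) {
  amb <- vapply(bin_maps, function(b) b$ambiguous, logical(1))
  if (any(amb)) {
    warning("dropping ambiguous loci: ",
            paste(names(bin_maps)[amb], collapse = ", "))
    bin_maps <- bin_maps[!amb]
  }
  peaks <- peaks[peaks$locus_id %in% names(bin_maps), , drop = FALSE]
  if (nrow(peaks) == 0) stop("no peaks at unambiguous loci")
  lookup <- function(size, bins) {
    if (is.na(size)) return(NA_integer_)
    hit <- which(size >= bins$lower & size <= bins$upper)
    if (length(hit) == 1) bins$label[hit] else NA_integer_
  }
  n_out <- 0L; n_peaks <- 0L
  calls <- peaks
  calls$allele_a <- NA_integer_; calls$allele_b <- NA_integer_
  for (lc in names(bin_maps)) {
    idx <- which(peaks$locus_id == lc)
    bins <- bin_maps[[lc]]$bins
    a <- vapply(peaks$size_a[idx], lookup, integer(1), bins = bins)
    b <- vapply(peaks$size_b[idx], lookup, integer(1), bins = bins)
    # homozygote convention: one observed peak -> duplicated label
    single <- is.na(peaks$size_b[idx]) & !is.na(a)
    b[single] <- a[single]
    # a peak that was present but unbinnable voids the whole call
    bad <- (!is.na(peaks$size_a[idx]) & is.na(a)) |
      (!is.na(peaks$size_b[idx]) & is.na(b))
    n_out <- n_out + sum((!is.na(peaks$size_a[idx]) & is.na(a))) +
      sum((!is.na(peaks$size_b[idx]) & is.na(b) & !single))
    n_peaks <- n_peaks + sum(!is.na(peaks$size_a[idx])) +
      sum(!is.na(peaks$size_b[idx]))
    a[bad] <- NA_integer_; b[bad] <- NA_integer_
    calls$allele_a[idx] <- a; calls$allele_b[idx] <- b
  }
  if (n_out > 0) {
    warning(n_out, " of ", n_peaks, " peaks fell outside all bins; ",
            "affected calls set to missing")
  }
  g <- genotype_matrix(calls[c("individual_id", "locus_id", "replicate",
                               "allele_a", "allele_b")])
  attr(g, "out_of_bin_rate") <- if (n_peaks) n_out / n_peaks else 0
  g
}
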
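#' Count occurrences of a primer in a read pool
#'
#' Exact-match occurrences of the primer or its reverse complement, summed
#' over all reads, overlapping matches included. Exact matching treats the
#' count as a proxy for genomic copy number: occurrences below the lower
#' screening bound suggest sequencing error in the primer site, occurrences
#' above the genome coverage suggest a multi-copy region.
#'
#' @param primer ACGT sequence, length >= 10.
#' @param reads data frame from [read_fastq()] or a character vector of
#'   sequences.
#' @return total match count (integer).
#' @export
count_primer_occurrences <- function(primer, reads) {
  if (is.data.frame(reads)) reads <- reads$sequence
  primer <- toupper(primer)
  if (!is_dna(primer)) stop("primer must contain only A,C,G,T")
  if (nchar(primer) < 10) stop("primer length must be >= 10")
  subj <- Biostrings::DNAStringSet(reads)
  rc <- revcomp(primer)
  n <- sum(Biostrings::vcountPattern(primer, subj))
  if (rc != primer) n <- n + sum(Biostrings::vcountPattern(rc, subj))
  as.integer(n)
}

#' Count occurrences for a table of primer pairs
#'
#' @param pairs data frame with `locus_id`, `forward`, `reverse` (see
#'   [read_primer_table()]).
#' @param reads read pool (data frame or character vector).
#' @return `pairs` with `fwd_count` and `rev_count` columns filled.
#' @export
count_primer_pairs <- function(pairs, reads) {
  pairs$fwd_count <- vapply(pairs$forward, count_primer_occurrences,
                            integer(1), reads = reads, USE.NAMES = FALSE)
  pairs$rev_count <- vapply(pairs$reverse, count_primer_occurrences,
                            integer(1), reads = reads, USE.NAMES = FALSE)
  pairs
}

#' Estimate genome coverage from single-copy-gene read depths
#'
#' Per-gene median depth (mean of the two central values for an even number
#' of positions), then the grand median of the per-gene medians, with the
#' min and max of the per-gene medians reported alongside. The grand median
#' is the default upper bound of the PAL keep-rule.
#'
#' @param depth_table named list mapping gene id to a numeric vector of
#'   per-position depths (see [read_depth_table()]).
#' @return an object of class `coverage_estimate`: list with
#'   `per_gene_median`, `grand_median`, `min`, `max`, `n_genes`.
#' @export
estimate_coverage <- function(depth_table) {
  if (length(depth_table) == 0) stop("empty depth table")
  if (any(vapply(depth_table, length, 1L) == 0)) {
    stop("every gene needs at least one position")
  }
  med <- vapply(depth_table, stats::median, numeric(1))
  structure(list(per_gene_median = med,
                 grand_median = stats::median(med),
                 min = min(med), max = max(med),
                 n_genes = sum(vapply(depth_table, function(d)
                   any(d > 0), logical(1)))),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf(
    "genome coverage: grand median %gx (min = %g, max = %g) over %d gene fragments\n",
    x$grand_median, x$min, x$max, length(x$per_gene_median)))
  invisible(x)
}

#' Apply the potentially-amplifiable-locus keep-rule
#'
#' A locus is kept iff both primer counts lie inside the inclusive band
#' `[min_count, max_count]`; loci with fewer occurrences of either primer
#' are likely sequencing errors, loci with more likely multi-copy regions.
#' `max_count` defaults to the estimated genome coverage rounded half up.
#'
#' @param pairs data frame with `locus_id`, `fwd_count`, `rev_count` (see
#'   [count_primer_pairs()]).
#' @param min_count lower inclusive bound (default 2).
#' @param max_count upper inclusive bound, or a `coverage_estimate` whose
#'   grand median is rounded half up.
#' @return data frame `locus_id`, `fwd_count`, `rev_count`, `kept`,
#'   `reason` (one of ok, fwd_low, fwd_high, rev_low, rev_high; the first
#'   failing bound in that order).
#' @export
filter_pals <- function(pairs, min_count = 2L, max_count) {
  if (inherits(max_count, "coverage_estimate")) {
    max_count <- as.integer(round_half_up(max_count$grand_median))
  }
  if (max_count < min_count) stop("max_count must be >= min_count")
  if (is.null(pairs$fwd_count) || is.null(pairs$rev_count)) {
    stop("primer counts must be populated before filtering")
  }
  reason <- rep("ok", nrow(pairs))
  reason[pairs$rev_count > max_count] <- "rev_high"
  reason[pairs$rev_count < min_count] <- "rev_low"
  reason[pairs$fwd_count > max_count] <- "fwd_high"
  reason[pairs$fwd_count < min_count] <- "fwd_low"
  data.frame(locus_id = pairs$locus_id,
             fwd_count = pairs$fwd_count, rev_count = pairs$rev_count,
             kept = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}
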
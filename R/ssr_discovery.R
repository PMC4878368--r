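#' Reverse complement of DNA strings
#'
#' @param x character vector of ACGTN sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# smallest period of a string: p | n with s == strrep(prefix p, n/p)
smallest_period <- function(m) {
  n <- nchar(m)
  for (p in seq_len(n)) {
    if (n %% p == 0 &&
        m == strrep(substr(m, 1, p), n %/% p)) return(p)
  }
  n
}

#' Canonical form of a repeat motif
#'
#' Two SSRs are the same marker class regardless of which strand was read or
#' where the repeat phase starts, so motifs are reduced to the
#' lexicographically smallest string among all cyclic rotations of the motif
#' and of its reverse complement (e.g. `"TG"`, `"GT"`, `"CA"` and `"AC"` all
#' canonicalize to `"AC"`).
#'
#' @param motif character vector of motifs, length 2-6, alphabet ACGT, not
#'   reducible to a shorter period (`"ATAT"` is rejected: it is 2 x `"AT"`).
#' @return character vector of canonical motifs.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n < 2 || n > 6) stop("motif length must be 2-6: ", m)
    if (!is_dna(m)) stop("motif must contain only A,C,G,T: ", m)
    if (smallest_period(m) < n) {
      stop("motif is reducible (period ", smallest_period(m), "): ", m)
    }
    rot <- function(s) vapply(seq_len(n) - 1L, function(i)
      paste0(substr(s, i + 1, n), substr(s, 1, i)), "")
    min(c(rot(m), rot(revcomp(m))))
  }, "", USE.NAMES = FALSE)
}

#' Scan one read for maximal perfect tandem repeats
#'
#' Reports every maximal perfect run of a 2-6 bp motif with at least
#' `min_units[kmer]` repeat units. Runs are maximal (extendable by no full
#' unit on either side); the reported footprint is the left-anchored
#' `kmer * units` bases, excluding any trailing partial unit. An `N` breaks
#' a run. A run whose motif is reducible to a shorter period is reported
#' only at the shorter period (a `(AC)x8` run is one dimer hit, not also a
#' tetramer hit), which also resolves equal-footprint ties in favour of the
#' smallest kmer.
#'
#' @param sequence read sequence (character scalar) or a one-row data frame
#'   from [read_fastq()].
#' @param min_units named vector mapping kmer (`"2"`..`"6"`) to the minimum
#'   repeat units.
#' @param read_id id recorded in the hits.
#' @return data frame of hits sorted by start: `read_id`, `kmer`, `motif`
#'   (as in the read), `canonical_motif`, `units`, `start`, `end` (0-based,
#'   half-open).
#' @export
scan_read <- function(sequence, min_units = msat_config()$min_units,
                      read_id = "read") {
  if (is.data.frame(sequence)) {
    read_id <- sequence$read_id[1]
    sequence <- sequence$sequence[1]
  }
  if (!all(c("2", "3", "4", "5", "6") %in% names(min_units))) {
    stop("min_units must be defined for every kmer in 2:6")
  }
  empty <- data.frame(read_id = character(0), kmer = integer(0),
                      motif = character(0), canonical_motif = character(0),
                      units = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (n < 4) return(empty)
  ch <- strsplit(toupper(sequence), "")[[1]]
  hits <- list()
  for (k in 2:6) {
    if (n < 2 * k) next
    # eq[i]: position i matches position i+k and neither is N
    eq <- ch[seq_len(n - k)] == ch[(k + 1):n] & ch[seq_len(n - k)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- r$lengths[j] + k          # total perfect-run length
      units <- span %/% k
      if (units < min_units[[as.character(k)]]) next
      s <- starts[j]                    # 1-based start in read
      motif <- paste(ch[s:(s + k - 1L)], collapse = "")
      if (smallest_period(motif) < k) next  # reported at the shorter period
      hits[[length(hits) + 1L]] <- data.frame(
        read_id = read_id, kmer = k, motif = motif,
        canonical_motif = canonical_motif(motif),
        units = units, start = s - 1L, end = s - 1L + k * units,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a pool of reads for perfect SSRs
#'
#' @param reads data frame from [read_fastq()] (columns `read_id`,
#'   `sequence`).
#' @param min_units per-kmer minimum repeat units (see [scan_read()]).
#' @return data frame of all hits, in read order then position order.
#' @export
scan_reads <- function(reads, min_units = msat_config()$min_units) {
  res <- lapply(seq_len(nrow(reads)), function(i) {
    scan_read(reads$sequence[i], min_units, read_id = reads$read_id[i])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- scan_read("", min_units)
  rownames(out) <- NULL
  out
}

#' Summarize SSR hits by kmer and canonical motif
#'
#' @param hits data frame of hits from [scan_read()]/[scan_reads()].
#' @return an object of class `repeat_summary`: a data frame of counts per
#'   (`kmer`, `canonical_motif`) with per-kmer totals in
#'   `attr(, "kmer_totals")` and the grand total in `attr(, "total")`.
#' @export
summarize_repeats <- function(hits) {
  if (nrow(hits) == 0) {
    out <- data.frame(kmer = integer(0), canonical_motif = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  } else {
    tab <- stats::aggregate(list(count = hits$kmer),
                            by = list(kmer = hits$kmer,
                                      canonical_motif = hits$canonical_motif),
                            FUN = length)
    out <- tab[order(tab$kmer, tab$canonical_motif), , drop = FALSE]
    rownames(out) <- NULL
  }
  kt <- tapply(out$count, factor(out$kmer, levels = 2:6), sum,
               default = 0L)
  structure(out, kmer_totals = as.integer(kt) |>
              stats::setNames(names(kt)),
            total = sum(out$count), class = c("repeat_summary",
                                              "data.frame"))
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat("SSR repeat summary:", attr(x, "total"), "hits\n")
  kt <- attr(x, "kmer_totals")
  cat("  per kmer:", paste(sprintf("%s-mer:%d", names(kt), kt),
                           collapse = " "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}
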
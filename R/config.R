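#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated object.
#' Defaults reproduce the reference workflow: per-kmer minimum repeat units
#' for discovery, the primer-occurrence keep-rule bounds for screening, the
#' gap-clustering and ambiguity parameters for allele binning, and the
#' Monte-Carlo / adjustment / rarefaction settings for characterization.
#'
#' @param min_units named integer vector mapping kmer length (as character
#'   `"2"`..`"6"`) to the minimum number of perfect repeat units an SSR must
#'   have to be reported.
#' @param min_primer_count lower inclusive bound on primer occurrences; loci
#'   with fewer occurrences of either primer are discarded as likely
#'   sequencing error.
#' @param max_primer_count upper inclusive bound on primer occurrences, or
#'   `NULL` to derive it from estimated genome coverage (rounded half up);
#'   loci above it likely sit in multi-copy regions.
#' @param gap_factor a new allele bin starts when the gap between adjacent
#'   sorted fragment sizes exceeds `gap_factor * motif_len` (bp).
#' @param ambiguity_threshold loci whose ambiguity score exceeds this are
#'   flagged as not clearly binnable and should be excluded.
#' @param hwe_B number of Monte-Carlo permutations for the HWE test.
#' @param adjust_method multiple-testing adjustment, `"holm"` or `"bh"`.
#' @param rarefaction_g standardized number of allele copies for rarefaction
#'   allelic richness, or `NULL` to use twice the smallest per-locus sample
#'   size in the data set.
#' @param half_call how to treat genotype rows with a single size present:
#'   `"invalid"` (flagged, treated as missing) or `"homozygote"`.
#' @param seed integer seed recorded in every output header and used for all
#'   stochastic steps.
#' @return an object of class `msat_config` (a validated list).
#' @examples
#' cfg <- msat_config(seed = 1)
#' cfg$min_units[["2"]]
#' @export
msat_config <- function(min_units = c("2" = 8L, "3" = 6L, "4" = 4L,
                                      "5" = 4L, "6" = 4L),
                        min_primer_count = 2L,
                        max_primer_count = NULL,
                        gap_factor = 0.5,
                        ambiguity_threshold = 0.25,
                        hwe_B = 1999L,
                        adjust_method = c("holm", "bh"),
                        rarefaction_g = NULL,
                        half_call = c("invalid", "homozygote"),
                        seed = 1L) {
  adjust_method <- match.arg(adjust_method)
  half_call <- match.arg(half_call)
  if (!all(c("2", "3", "4", "5", "6") %in% names(min_units))) {
    stop("min_units must be defined for every kmer in 2:6")
  }
  if (any(min_units < 1)) stop("min_units must be positive")
  if (min_primer_count < 0) stop("min_primer_count must be non-negative")
  if (!is.null(max_primer_count) && max_primer_count < min_primer_count) {
    stop("max_primer_count must be >= min_primer_count")
  }
  if (gap_factor <= 0) stop("gap_factor must be positive")
  if (ambiguity_threshold < 0) stop("ambiguity_threshold must be >= 0")
  if (hwe_B < 1) stop("hwe_B must be >= 1")
  if (!is.null(rarefaction_g) && rarefaction_g < 1) {
    stop("rarefaction_g must be >= 1")
  }
  structure(list(
    min_units = stats::setNames(
      as.integer(min_units[c("2", "3", "4", "5", "6")]),
      c("2", "3", "4", "5", "6")),
    min_primer_count = as.integer(min_primer_count),
    max_primer_count = if (is.null(max_primer_count)) NULL else
      as.integer(max_primer_count),
    gap_factor = gap_factor,
    ambiguity_threshold = ambiguity_threshold,
    hwe_B = as.integer(hwe_B),
    adjust_method = adjust_method,
    rarefaction_g = if (is.null(rarefaction_g)) NULL else
      as.integer(rarefaction_g),
    half_call = half_call,
    seed = as.integer(seed)
  ), class = "msat_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [msat_config()]. `min_units` may be given as a YAML map of kmer to units.
#'
#' @param path YAML file path.
#' @return an `msat_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(msat_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$min_units)) raw$min_units <- unlist(raw$min_units)
  do.call(msat_config, raw)
}

#' @export
print.msat_config <- function(x, ...) {
  cat("msatkit run configuration\n")
  cat("  min repeat units:",
      paste(sprintf("%s-mer:%d", names(x$min_units), x$min_units),
            collapse = " "), "\n")
  cat("  primer occurrence bounds: [", x$min_primer_count, ", ",
      if (is.null(x$max_primer_count)) "coverage-derived" else
        x$max_primer_count, "]\n", sep = "")
  cat("  binning: gap_factor", x$gap_factor,
      "ambiguity_threshold", x$ambiguity_threshold, "\n")
  cat("  HWE: B =", x$hwe_B, "; adjustment:", x$adjust_method, "\n")
  cat("  rarefaction g:",
      if (is.null(x$rarefaction_g)) "2 x min per-locus n" else
        x$rarefaction_g, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
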
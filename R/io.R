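#' Read sequencing reads from a FASTQ file
#'
#' Plain or gzip-compressed FASTQ. Lowercase bases are uppercased; read ids
#' are the full header line after `@`. Parsing is delegated to Biostrings.
#'
#' @param path FASTQ file, optionally `.gz`.
#' @return a data frame with columns `read_id`, `sequence`, `quality`
#'   (quality is `NA` when the file carries none).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_fastq_lines(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  res <- data.frame(
    read_id = if (length(x)) names(x) else character(0),
    sequence = as.character(x),
    quality = if (length(x)) qual else character(0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  message(nrow(res), " reads parsed from ", basename(path))
  res
}

# cheap structural check on plain-text files so a truncated record can be
# reported with its line number (Biostrings' own message lacks it)
validate_fastq_lines <- function(path) {
  if (grepl("\\.gz$", path)) return(invisible(TRUE))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(invisible(TRUE))
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: truncated record starting at line ",
         4 * (length(lines) %/% 4) + 1, " of ", path)
  }
  heads <- seq(1, length(lines), by = 4)
  bad <- which(!startsWith(lines[heads], "@"))
  if (length(bad)) {
    stop("malformed FASTQ: expected '@' header at line ", heads[bad[1]])
  }
  mism <- which(nchar(lines[heads + 1]) != nchar(lines[heads + 3]))
  if (length(mism)) {
    stop("malformed FASTQ: sequence/quality length mismatch at line ",
         heads[mism[1]] + 3)
  }
  invisible(TRUE)
}

#' Write reads to a FASTQ file
#'
#' Inverse of [read_fastq()]: `read_fastq(write_fastq(x, f))` is the
#' identity on (id, sequence, quality). Compressed output when `path` ends
#' in `.gz`.
#'
#' @param reads data frame with `read_id`, `sequence` and optional `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  qual <- if (!is.null(reads$quality) && !anyNA(reads$quality)) {
    Biostrings::BStringSet(reads$quality)
  } else {
    Biostrings::BStringSet(vapply(nchar(reads$sequence), function(n)
      strrep("I", n), ""))
  }
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Diploid genotype matrix
#'
#' Container for per-individual, per-locus, per-replicate diploid calls with
#' explicit missingness. Calls are stored long (one row per individual x
#' locus x replicate); allele labels are binned fragment sizes in bp.
#'
#' @param calls data frame with columns `individual_id`, `locus_id`,
#'   `replicate`, `allele_a`, `allele_b` (both `NA` = missing call). A
#'   half-call (exactly one allele present) is kept but flagged invalid.
#' @param individuals,loci optional orderings; defaults to order of first
#'   appearance in `calls`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individuals = NULL, loci = NULL) {
  need <- c("individual_id", "locus_id", "replicate", "allele_a", "allele_b")
  if (!all(need %in% names(calls))) {
    stop("calls must have columns ", paste(need, collapse = ", "))
  }
  calls <- calls[need]
  calls$individual_id <- as.character(calls$individual_id)
  calls$locus_id <- as.character(calls$locus_id)
  calls$replicate <- as.integer(calls$replicate)
  if (any(calls$replicate < 1L)) stop("replicate must be >= 1")
  key <- paste(calls$individual_id, calls$locus_id, calls$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (individual, locus, replicate): ",
         key[which(duplicated(key))[1]])
  }
  # normalize unordered pairs; a one-sided pair stays one-sided (half-call)
  a <- calls$allele_a; b <- calls$allele_b
  swap <- !is.na(a) & !is.na(b) & a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  one <- is.na(a) & !is.na(b)
  a[one] <- b[one]; b[one] <- NA
  calls$allele_a <- a; calls$allele_b <- b
  calls$valid <- is.na(a) == is.na(b)  # both present or both absent
  if (is.null(individuals)) individuals <- unique(calls$individual_id)
  if (is.null(loci)) loci <- unique(calls$locus_id)
  if (!all(calls$individual_id %in% individuals)) {
    stop("calls contain individuals not in `individuals`")
  }
  if (!all(calls$locus_id %in% loci)) stop("unknown locus in calls")
  structure(list(calls = calls, individuals = individuals, loci = loci),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) {
  c(length(x$individuals), length(x$loci))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x)
  nrep <- max(x$calls$replicate)
  miss <- mean(is.na(x$calls$allele_a) | !x$calls$valid)
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci (%d replicate%s), %.1f%% missing calls\n",
    d[1], d[2], nrep, if (nrep > 1) "s" else "", 100 * miss))
  invisible(x)
}

#' Extract the complete genotypes of one locus
#'
#' @param x a `genotype_matrix`.
#' @param locus locus id.
#' @param replicate replicate number.
#' @return integer matrix with columns `a`, `b`, one row per individual with
#'   a complete (two-allele, valid) call.
#' @export
locus_genotypes <- function(x, locus, replicate = 1L) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!locus %in% x$loci) stop("unknown locus: ", locus)
  cc <- x$calls
  cc <- cc[cc$locus_id == locus & cc$replicate == replicate &
             cc$valid & !is.na(cc$allele_a), , drop = FALSE]
  m <- cbind(a = cc$allele_a, b = cc$allele_b)
  rownames(m) <- cc$individual_id
  m
}

#' Read a genotype table from CSV
#'
#' Long format (default): columns individual, locus, replicate, size_a,
#' size_b; missing encoded as empty cell or `NA`. Wide format: one
#' individual per row, a `<locus>_a`/`<locus>_b` column pair per locus;
#' normalized to long on read. Column names are remappable via `col_map`
#' because deposited supplementary tables differ in their headers.
#'
#' @param path CSV path (comment lines starting `#` ignored).
#' @param format `"long"` or `"wide"`.
#' @param col_map named character vector remapping the long-format columns,
#'   e.g. `c(individual_id = "ID", locus_id = "Locus")`.
#' @param half_call `"invalid"` (default) keeps single-size rows flagged
#'   invalid; `"homozygote"` duplicates the single size.
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, format = c("long", "wide"),
                                col_map = NULL,
                                half_call = c("invalid", "homozygote")) {
  format <- match.arg(format)
  half_call <- match.arg(half_call)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  if (format == "wide") {
    df <- wide_to_long(df)
  }
  std <- c(individual_id = "individual_id", locus_id = "locus_id",
           replicate = "replicate", allele_a = "size_a", allele_b = "size_b")
  if (!is.null(col_map)) std[names(col_map)] <- col_map
  missing_cols <- setdiff(unname(std[c("individual_id", "locus_id")]),
                          names(df))
  if (length(missing_cols)) {
    stop("genotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  calls <- data.frame(
    individual_id = df[[std[["individual_id"]]]],
    locus_id = df[[std[["locus_id"]]]],
    replicate = if (std[["replicate"]] %in% names(df))
      df[[std[["replicate"]]]] else 1L,
    allele_a = df[[std[["allele_a"]]]],
    allele_b = df[[std[["allele_b"]]]],
    stringsAsFactors = FALSE
  )
  if (half_call == "homozygote") {
    one <- xor(is.na(calls$allele_a), is.na(calls$allele_b))
    only <- ifelse(is.na(calls$allele_a), calls$allele_b, calls$allele_a)
    calls$allele_a[one] <- only[one]
    calls$allele_b[one] <- only[one]
  }
  genotype_matrix(calls)
}

# wide: individual_id + <locus>_a/<locus>_b pairs -> long
wide_to_long <- function(df) {
  idcol <- names(df)[1]
  acols <- grep("_a$", names(df), value = TRUE)
  loci <- sub("_a$", "", acols)
  out <- do.call(rbind, lapply(loci, function(lc) {
    data.frame(individual_id = df[[idcol]], locus_id = lc, replicate = 1L,
               size_a = df[[paste0(lc, "_a")]],
               size_b = df[[paste0(lc, "_b")]], stringsAsFactors = FALSE)
  }))
  out
}

#' Write a genotype matrix to CSV
#'
#' Long format; missing alleles become empty cells so that the missingness
#' pattern round-trips exactly. A comment header records version, config
#' hash and seed.
#'
#' @param x a `genotype_matrix`.
#' @param path output CSV.
#' @param config,seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, config = NULL, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  out <- x$calls[c("individual_id", "locus_id", "replicate",
                   "allele_a", "allele_b")]
  names(out)[4:5] <- c("size_a", "size_b")
  write_table_with_header(out, path, sep = ",", config = config, seed = seed)
}

#' Read raw fragment-size peak calls from CSV
#'
#' Expected columns: `individual_id`, `locus_id`, `replicate`, `size_a`,
#' `size_b` (fractional bp; `size_b` empty for single-peak calls).
#'
#' @param path CSV path.
#' @return validated data frame (`size_a <= size_b` where both present).
#' @export
read_peak_calls <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  need <- c("individual_id", "locus_id", "replicate", "size_a", "size_b")
  if (!all(need %in% names(df))) {
    stop("peak-call table must have columns ", paste(need, collapse = ", "))
  }
  swap <- !is.na(df$size_a) & !is.na(df$size_b) & df$size_a > df$size_b
  tmp <- df$size_a[swap]; df$size_a[swap] <- df$size_b[swap]
  df$size_b[swap] <- tmp
  if (any(c(df$size_a, df$size_b) <= 0, na.rm = TRUE)) {
    stop("fragment sizes must be positive")
  }
  df[need]
}

#' Read a primer-pair table
#'
#' TSV with columns `locus_id`, `forward`, `reverse` (5'->3' sequences).
#'
#' @param path TSV path.
#' @return data frame of primer pairs.
#' @export
read_primer_table <- function(path) {
  df <- read_table_skip_header(path)
  need <- c("locus_id", "forward", "reverse")
  if (!all(need %in% names(df))) {
    stop("primer table must have columns ", paste(need, collapse = ", "))
  }
  df$forward <- toupper(df$forward)
  df$reverse <- toupper(df$reverse)
  if (!is_dna(c(df$forward, df$reverse))) {
    stop("primers must be non-empty ACGT sequences")
  }
  df[need]
}

#' Read a per-gene per-position read-depth table
#'
#' TSV with columns `gene_id`, `position`, `depth`; returns the list-of-depth
#' layout [estimate_coverage()] consumes.
#'
#' @param path TSV path.
#' @return named list mapping gene id to numeric depth vector.
#' @export
read_depth_table <- function(path) {
  df <- read_table_skip_header(path)
  need <- c("gene_id", "position", "depth")
  if (!all(need %in% names(df))) {
    stop("depth table must have columns ", paste(need, collapse = ", "))
  }
  split(df$depth, df$gene_id)
}

#' Write per-locus characterization summaries to TSV
#'
#' One row per locus, columns: locus, n, range_min, range_max, n_alleles,
#' obs_het, exp_het, hwe_p_raw, hwe_p_adj, allelic_richness, null_freq,
#' error_rate. Floating-point columns are printed to `digits` decimals
#' (default 2, the conventional reporting precision for these tables);
#' internal computation is full precision.
#'
#' @param summaries a `locus_summary` object or its data frame.
#' @param path output TSV.
#' @param digits reporting precision for proportions and richness.
#' @param config,seed recorded in the comment header.
#' @return `path`, invisibly.
#' @export
write_locus_summaries <- function(summaries, path, digits = 2,
                                  config = NULL, seed = NULL) {
  df <- as.data.frame(summaries)
  cols <- c("locus", "n", "range_min", "range_max", "n_alleles", "obs_het",
            "exp_het", "hwe_p_raw", "hwe_p_adj", "allelic_richness",
            "null_freq", "error_rate")
  if (nrow(df) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                        cols))
  }
  df <- df[cols]
  numcols <- c("obs_het", "exp_het", "hwe_p_raw", "hwe_p_adj",
               "allelic_richness", "null_freq", "error_rate")
  for (cc in numcols) {
    v <- sprintf("%.*f", digits, round_half_up(df[[cc]], digits))
    v[is.na(df[[cc]])] <- NA
    df[[cc]] <- v
  }
  write_table_with_header(df, path, sep = "\t", config = config, seed = seed)
}
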
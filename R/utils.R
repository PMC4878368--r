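#' @keywords internal
"_PACKAGE"

# Reversible RNG scoping: run `code` under `seed` without disturbing the
# caller's RNG state. All stochastic functions in the package route
# through this so results are reproducible call-by-call.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# 32-bit FNV-1a over a character scalar, done in doubles (R has no native
# unsigned 32-bit integers). Used for config hashes in output headers and
# for deriving named sub-stream seeds.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of two non-negative doubles < 2^32, bytewise
bitwXor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Derive a named sub-stream seed from a master seed
#'
#' Each simulator component draws from its own named stream so that adding a
#' new stream to a pipeline never perturbs the output of existing ones.
#' The derived seed is always a valid 32-bit R seed.
#'
#' @param seed master integer seed.
#' @param name stream name (e.g. `"reads"`, `"genotypes"`).
#' @return an integer seed in `[0, 2^31)`.
#' @export
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer(bitwXor32(fnv1a32(name), seed %% 4294967296) %% 2147483647)
}

# Comment header stamped at the top of every tabular output file:
# tool version, config hash, seed. FASTQ has no comment syntax, so the
# header applies to TSV/CSV outputs only.
output_header <- function(config = NULL, seed = NULL) {
  ver <- as.character(utils::packageVersion("msatkit"))
  hash <- if (is.null(config)) "none" else {
    h <- fnv1a32(paste(deparse(config), collapse = ""))
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }
  c(
    sprintf("# msatkit %s", ver),
    sprintf("# config_hash: %s", hash),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed))
  )
}

write_table_with_header <- function(df, path, sep = "\t", config = NULL,
                                    seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config, seed), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_table_skip_header <- function(path, sep = "\t", ...) {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

# round half up (base round() rounds half to even); labels and coverage
# bounds use the conventional half-up rule so 8.5 -> 9, 100.5 -> 101
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

is_dna <- function(x) {
  all(grepl("^[ACGT]+$", x))
}
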
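# Internal helpers. The package works in a single internal DNA alphabet
# (A,C,G,T); readers accept RNA (U) and normalize, user-facing tables report
# small-RNA sequences back in RNA.

BASES_DNA <- c("A", "C", "G", "T")
BASES_RNA <- c("A", "C", "G", "U")

normalize_seq <- function(x) chartr("U", "T", toupper(x))

dna_to_rna <- function(x) chartr("T", "U", x)

is_valid_seq <- function(x) nchar(x) > 0L & grepl("^[ACGT]+$", x)

# Deterministic, locale-independent ordering for character keys.
ord <- function(...) order(..., method = "radix")

#' Derive independent substream seeds from one top-level seed
#'
#' One user-facing seed deterministically spawns one seed per stochastic
#' stage, so stages can be re-run or reordered without perturbing each
#' other's streams.
#'
#' @param seed Integer scalar.
#' @param n Number of substream seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

log_msg <- function(level, ..., config_level = getOption("p4ce.log_level", "info")) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L, quiet = 5L)
  if (levels[[level]] >= levels[[config_level]]) {
    message(sprintf("[p4ce %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}
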
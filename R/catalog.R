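#' Catalog filter parameters
#'
#' The published filtering rule is strict: precursors longer than 30 nt AND
#' with more than 50 reads are retained (exclusive bounds, exactly as
#' printed; length 30 or count 50 are excluded).
#'
#' @param min_length_exclusive Retain species with length strictly greater
#'   than this (default 30).
#' @param min_reads_exclusive Retain species with read count strictly
#'   greater than this (default 50).
#' @export
catalog_params <- function(min_length_exclusive = 30L, min_reads_exclusive = 50L) {
  stopifnot(min_length_exclusive >= 0L, min_reads_exclusive >= 0L)
  structure(list(min_length_exclusive = as.integer(min_length_exclusive),
                 min_reads_exclusive = as.integer(min_reads_exclusive)),
            class = "catalog_params")
}

#' Combine precursor reads sharing a 5' end into P4RNA species
#'
#' Reads are grouped by identical (cluster, 5' position, strand) anchor.
#' Each group becomes one P4RNA whose representative sequence is the
#' longest member read (ties broken by the lexicographically smallest
#' sequence) and whose read count is the sum of member counts. A read that
#' maps to several anchors contributes its full count to each.
#'
#' @param reads data.frame with `id`, `sequence`, `count`.
#' @param hits Output of [map_to_references()] against cluster references.
#' @return A P4RNA catalog data.frame: `id`, `cluster`, `position` (0-based
#'   5' offset on the cluster), `strand`, `length`, `read_count`,
#'   `sequence`, ordered by anchor.
#' @export
collapse_by_five_prime <- function(reads, hits) {
  if (nrow(hits) == 0L) return(empty_catalog())
  m <- match(hits$read_id, reads$id)
  if (anyNA(m)) stop("hits reference read ids absent from the read table")
  df <- data.frame(cluster = hits$reference_id,
                   position = hits$offset,
                   strand = "+",
                   sequence = normalize_seq(reads$sequence[m]),
                   count = reads$count[m],
                   stringsAsFactors = FALSE)
  key <- paste(df$cluster, df$position, df$strand, sep = "\r")
  # representative = longest sequence, ties -> lexicographically smallest
  o <- ord(key, -nchar(df$sequence), df$sequence)
  df <- df[o, , drop = FALSE]
  key <- key[o]
  first <- !duplicated(key)
  counts <- rowsum(df$count, group = key, reorder = FALSE)
  rep_rows <- df[first, , drop = FALSE]
  out <- data.frame(cluster = rep_rows$cluster,
                    position = rep_rows$position,
                    strand = rep_rows$strand,
                    length = nchar(rep_rows$sequence),
                    read_count = as.integer(counts[, 1L]),
                    sequence = rep_rows$sequence,
                    stringsAsFactors = FALSE)
  out <- out[ord(out$cluster, out$position, out$strand), , drop = FALSE]
  out <- cbind(id = sprintf("p4_%05d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

empty_catalog <- function() {
  data.frame(id = character(), cluster = character(), position = integer(),
             strand = character(), length = integer(), read_count = integer(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' Apply length and abundance filters to a P4RNA catalog
#'
#' @param catalog Output of [collapse_by_five_prime()].
#' @param params A [catalog_params()] object.
#' @return The retained subset, ordered by anchor.
#' @export
filter_catalog <- function(catalog, params = catalog_params()) {
  stopifnot(inherits(params, "catalog_params"))
  keep <- catalog$length > params$min_length_exclusive &
    catalog$read_count > params$min_reads_exclusive
  out <- catalog[keep, , drop = FALSE]
  out <- out[ord(out$cluster, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a filtered P4RNA catalog from reads and cluster references
#'
#' Maps reads to the clusters (exact, sense strand, fully contained),
#' combines reads sharing a 5' end, and applies the catalog filters.
#'
#' @inheritParams collapse_by_five_prime
#' @param refs Cluster [reference_set()].
#' @param params A [catalog_params()] object.
#' @export
build_catalog <- function(reads, refs, params = catalog_params()) {
  hits <- map_to_references(reads, refs)
  filter_catalog(collapse_by_five_prime(reads, hits), params)
}

#' Write a P4RNA catalog as TSV (and optionally FASTA)
#'
#' Sequences are reported in the RNA alphabet in the TSV; the FASTA (for
#' downstream read mapping) is written in DNA.
#'
#' @param catalog A catalog data.frame.
#' @param tsv_path Output TSV path.
#' @param fasta_path Optional output FASTA path.
#' @export
write_catalog <- function(catalog, tsv_path, fasta_path = NULL) {
  out <- catalog
  out$sequence <- dna_to_rna(out$sequence)
  write_tsv(out, tsv_path)
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(catalog$sequence)
    names(ss) <- catalog$id
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(tsv_path)
}

#' Read a P4RNA catalog TSV
#'
#' @param path Catalog TSV written by [write_catalog()].
#' @export
read_catalog <- function(path) {
  out <- read_tsv(path)
  out$sequence <- normalize_seq(out$sequence)
  out
}
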
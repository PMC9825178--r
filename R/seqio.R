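#' Read collapsed small-RNA reads from FASTA or FASTQ
#'
#' Small-RNA libraries are usually stored collapsed: each record is a
#' distinct sequence and its read multiplicity is carried in the header as
#' an `_xN` suffix (e.g. `read7_x153`). Records without the suffix get
#' count 1. Sequences are normalized to an internal DNA alphabet (U -> T);
#' records containing any symbol outside {A,C,G,U,T} are rejected at parse
#' with a warning.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format `"auto"` (by extension), `"fasta"`, or `"fastq"`.
#' @return A data.frame with columns `id`, `sequence` (DNA alphabet),
#'   `count` (positive integer), carrying the number of rejected records in
#'   attribute `rejected`.
#' @export
read_small_rna <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  ss <- Biostrings::readBStringSet(path, format = format)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  counts <- rep(1L, length(ids))
  has_x <- grepl("_x\\d+$", ids)
  counts[has_x] <- as.integer(sub("^.*_x(\\d+)$", "\\1", ids[has_x]))
  seqs <- normalize_seq(as.character(ss))
  keep <- is_valid_seq(seqs) & counts >= 1L
  if (any(!keep)) {
    warning(sprintf("rejected %d read(s) with invalid alphabet or count", sum(!keep)))
  }
  out <- data.frame(id = ids[keep], sequence = unname(seqs[keep]),
                    count = counts[keep], stringsAsFactors = FALSE)
  attr(out, "rejected") <- sum(!keep)
  out
}

#' Write collapsed small-RNA reads to FASTA
#'
#' Headers are written as `id_xN` unless the id already ends in the
#' matching `_xN` suffix.
#'
#' @param reads data.frame with `id`, `sequence`, `count`.
#' @param path Output FASTA path.
#' @export
write_small_rna <- function(reads, path) {
  suffix <- paste0("_x", reads$count)
  ids <- ifelse(endsWith(reads$id, suffix), reads$id, paste0(reads$id, suffix))
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a reference set
#'
#' @param entries Named character vector of reference sequences; ids must be
#'   unique, sequences non-empty.
#' @param kind `"cluster"` (Pol IV cluster sequences) or `"p4rna"`
#'   (precursor catalog sequences).
#' @return A `reference_set` object.
#' @export
reference_set <- function(entries, kind = c("cluster", "p4rna")) {
  kind <- match.arg(kind)
  stopifnot(length(entries) > 0L, !is.null(names(entries)),
            !anyDuplicated(names(entries)), all(nzchar(names(entries))))
  entries <- normalize_seq(entries)
  if (!all(is_valid_seq(entries))) stop("reference sequences must be non-empty A/C/G/U/T strings")
  structure(list(entries = entries, kind = kind), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set: %d %s sequence(s), widths %d-%d>\n",
              length(x$entries), x$kind,
              min(nchar(x$entries)), max(nchar(x$entries))))
  invisible(x)
}

#' Read a reference set from FASTA
#'
#' @param path FASTA path.
#' @inheritParams reference_set
#' @export
read_reference_fasta <- function(path, kind = c("cluster", "p4rna")) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  reference_set(stats::setNames(as.character(ss), ids), kind = match.arg(kind))
}

#' Extract cluster sequences from BED intervals and a genome FASTA
#'
#' Intervals follow the standard BED convention (0-based, half-open).
#' Clusters are named from the BED name column when present, else
#' `chrom:start-end`.
#'
#' @param bed_path BED file of Pol IV cluster intervals.
#' @param genome_fasta Genome (or cluster scaffold) FASTA.
#' @return A `reference_set` of kind `"cluster"`.
#' @export
clusters_from_bed <- function(bed_path, genome_fasta) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chr %in% names(genome))) {
    stop("BED chromosomes missing from genome FASTA: ",
         paste(setdiff(chr, names(genome)), collapse = ", "))
  }
  seqs <- as.character(Biostrings::subseq(
    genome[chr],
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)))
  ids <- if (!is.null(gr$name) && all(!is.na(gr$name)) && !anyDuplicated(gr$name)) {
    as.character(gr$name)
  } else {
    sprintf("%s:%d-%d", chr, GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  }
  reference_set(stats::setNames(seqs, ids), kind = "cluster")
}

#' Trim a 3' sequencing adapter from read sequences
#'
#' A read is trimmed when the full adapter occurs inside it (everything from
#' the first occurrence onward is removed) or when a prefix of the adapter
#' of at least `min_overlap` nt matches the read's 3' end exactly. Untrimmed
#' reads are returned unchanged and flagged, not discarded.
#'
#' @param sequences Character vector of read sequences (DNA or RNA).
#' @param adapter Adapter sequence; default is the TruSeq small-RNA 3'
#'   adapter.
#' @param min_overlap Minimum adapter-prefix length for a 3'-end match
#'   (default 8).
#' @return data.frame with `sequence` (trimmed, DNA alphabet) and logical
#'   `trimmed`.
#' @export
trim_adapter <- function(sequences, adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_overlap = 8L) {
  stopifnot(nzchar(adapter), min_overlap >= 1L)
  seqs <- normalize_seq(sequences)
  if (!all(is_valid_seq(seqs))) stop("reads must be non-empty A/C/G/U/T strings")
  adapter <- normalize_seq(adapter)
  trimmed <- rep(FALSE, length(seqs))

  # full adapter occurrence anywhere: cut at first occurrence
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  hit <- pos > 0L
  seqs[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
  trimmed[hit] <- TRUE

  # partial adapter at the 3' end: longest adapter prefix >= min_overlap
  max_k <- min(nchar(adapter) - 1L, max(nchar(seqs), 0L))
  k <- max_k
  while (k >= min_overlap) {
    pre <- substr(adapter, 1L, k)
    idx <- !trimmed & nchar(seqs) >= k & endsWith(seqs, pre)
    if (any(idx)) {
      seqs[idx] <- substr(seqs[idx], 1L, nchar(seqs[idx]) - k)
      trimmed[idx] <- TRUE
    }
    k <- k - 1L
  }
  data.frame(sequence = seqs, trimmed = trimmed, stringsAsFactors = FALSE)
}

#' Trim adapters across a read table and drop too-short trimmed reads
#'
#' @param reads data.frame with `id`, `sequence`, `count`.
#' @inheritParams trim_adapter
#' @param min_length Trimmed reads shorter than this are discarded
#'   (default 15 nt).
#' @return The read table with trimmed sequences and a `trimmed` flag;
#'   attribute `discarded` counts dropped species.
#' @export
trim_reads <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                       min_overlap = 8L, min_length = 15L) {
  tr <- trim_adapter(reads$sequence, adapter = adapter, min_overlap = min_overlap)
  out <- reads
  out$sequence <- tr$sequence
  out$trimmed <- tr$trimmed
  drop <- tr$trimmed & nchar(tr$sequence) < min_length
  res <- out[!drop, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "discarded") <- sum(drop)
  res
}

#' Find every exact occurrence of reads within reference sequences
#'
#' Exact, ungapped, zero-mismatch, sense-strand matching only. Offsets are
#' 0-based; a hit is `anchored` when it starts at the reference's 5' end.
#' Hits are ordered by read, then reference id, then offset.
#'
#' Matching enumerates every reference window at each read length present
#' and joins it against the read sequences, so runtime scales with total
#' reference length times the number of distinct read lengths rather than
#' with the number of reads.
#'
#' @param reads data.frame with `id`, `sequence` (and optionally `count`),
#'   or a character vector of sequences.
#' @param refs A [reference_set()].
#' @return data.frame with `read_id`, `reference_id`, `offset`, `anchored`.
#' @export
map_to_references <- function(reads, refs) {
  stopifnot(inherits(refs, "reference_set"))
  if (is.character(reads)) {
    reads <- data.frame(id = if (!is.null(names(reads))) names(reads) else
                          sprintf("read%d", seq_along(reads)),
                        sequence = unname(reads), stringsAsFactors = FALSE)
  }
  seqs <- normalize_seq(reads$sequence)
  if (!all(is_valid_seq(seqs))) stop("reads must be non-empty A/C/G/U/T strings")
  ref_seq <- refs$entries
  ref_ids <- names(ref_seq)
  ref_w <- nchar(ref_seq)

  pieces <- list()
  for (L in sort(unique(nchar(seqs)))) {
    ri <- which(ref_w >= L)
    if (length(ri) == 0L) next
    n_win <- ref_w[ri] - L + 1L
    widx <- rep(ri, n_win)
    starts <- sequence(n_win)
    windows <- substring(ref_seq[widx], starts, starts + L - 1L)
    q <- which(nchar(seqs) == L)
    # one read sequence may occur in many windows; join window -> read rows
    m <- match(windows, seqs[q])
    # handle duplicate read sequences of the same length
    dup <- q[duplicated(seqs[q])]
    hit <- !is.na(m)
    if (!any(hit)) next
    base <- data.frame(read_row = q[m[hit]], ref_row = widx[hit],
                       offset = starts[hit] - 1L)
    if (length(dup) > 0L) {
      extra <- lapply(dup, function(r) {
        w <- which(windows == seqs[r])
        if (length(w) == 0L) return(NULL)
        data.frame(read_row = r, ref_row = widx[w], offset = starts[w] - 1L)
      })
      base <- rbind(base, do.call(rbind, extra))
    }
    pieces[[length(pieces) + 1L]] <- base
  }
  if (length(pieces) == 0L) {
    return(data.frame(read_id = character(), reference_id = character(),
                      offset = integer(), anchored = logical(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, pieces)
  out <- data.frame(read_id = reads$id[hits$read_row],
                    reference_id = ref_ids[hits$ref_row],
                    offset = hits$offset,
                    stringsAsFactors = FALSE)
  out$anchored <- out$offset == 0L
  out <- out[ord(match(out$read_id, reads$id), out$reference_id, out$offset), ,
             drop = FALSE]
  out <- out[!duplicated(out[c("read_id", "reference_id", "offset")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only 5'-anchored hits
#'
#' Retains hits whose read 5' end aligns exactly with the reference 5' end
#' (offset 0).
#'
#' @param hits Output of [map_to_references()].
#' @export
anchored_filter <- function(hits) {
  out <- hits[hits$offset == 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
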
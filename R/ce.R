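#' Count AGO-bound siRNA reads anchored at each P4RNA's 5' end
#'
#' A siRNA read counts toward a P4RNA only when it is an exact prefix of
#' the precursor sequence (5' ends aligned, sense strand, zero mismatches).
#' By default a siRNA that is a prefix of k precursors contributes its full
#' count to each of the k; `weight = "fractional"` divides the count by k
#' instead.
#'
#' @param catalog Filtered P4RNA catalog.
#' @param sirna_reads data.frame with `sequence` and `count`.
#' @param weight `"full"` (default) or `"fractional"` multi-mapping weight.
#' @param length_window Optional integer vector; only siRNA reads whose
#'   length falls in the window are counted (default: no restriction).
#' @return Named numeric vector, one entry per catalog P4RNA (zero when no
#'   siRNA matches).
#' @export
count_anchored_sirnas <- function(catalog, sirna_reads,
                                  weight = c("full", "fractional"),
                                  length_window = NULL) {
  weight <- match.arg(weight)
  stopifnot(nrow(catalog) > 0L)
  counts <- stats::setNames(numeric(nrow(catalog)), catalog$id)
  if (nrow(sirna_reads) == 0L) return(counts)
  seqs <- normalize_seq(sirna_reads$sequence)
  n <- sirna_reads$count
  if (!is.null(length_window)) {
    keep <- nchar(seqs) %in% length_window
    seqs <- seqs[keep]; n <- n[keep]
  }
  if (length(seqs) == 0L) return(counts)
  # collapse identical siRNA sequences
  agg <- rowsum(n, group = seqs)
  sseq <- rownames(agg)
  scount <- agg[, 1L]
  pairs <- list()
  for (L in sort(unique(nchar(sseq)))) {
    qi <- which(nchar(sseq) == L)
    ci <- which(nchar(catalog$sequence) >= L)
    if (length(ci) == 0L) next
    pre <- substr(catalog$sequence[ci], 1L, L)
    m <- match(pre, sseq[qi])
    hit <- !is.na(m)
    if (!any(hit)) next
    pairs[[length(pairs) + 1L]] <- data.frame(cat = ci[hit], sirna = qi[m[hit]])
  }
  if (length(pairs) == 0L) return(counts)
  pr <- do.call(rbind, pairs)
  w <- scount[pr$sirna]
  if (weight == "fractional") {
    k <- table(pr$sirna)
    w <- w / as.integer(k[as.character(pr$sirna)])
  }
  acc <- rowsum(w, group = pr$cat)
  counts[as.integer(rownames(acc))] <- acc[, 1L]
  names(counts) <- catalog$id
  counts
}

#' Compute per-P4RNA conversion efficiency
#'
#' CE is the raw ratio of AGO-bound siRNA reads to precursor reads for the
#' same 5'-anchored sequence; no library-depth normalization is applied.
#'
#' @param counts Output of [count_anchored_sirnas()].
#' @param catalog Filtered P4RNA catalog.
#' @return data.frame of CE records: `p4rna_id`, `p4rna_reads`,
#'   `sirna_reads`, `ce` (bins unassigned).
#' @export
compute_ce <- function(counts, catalog) {
  if (any(catalog$read_count <= 0L)) stop("P4RNA read counts must be positive")
  m <- counts[catalog$id]
  m[is.na(m)] <- 0
  data.frame(p4rna_id = catalog$id,
             p4rna_reads = catalog$read_count,
             sirna_reads = unname(m),
             ce = unname(m) / catalog$read_count,
             stringsAsFactors = FALSE)
}

#' Partition CE records into equal-size ascending bins
#'
#' Records are sorted by ascending CE (ties broken by `p4rna_id` for
#' determinism) and split into `n_bins` contiguous groups whose sizes
#' differ by at most one; any remainder goes to the lowest-numbered bins,
#' so bin 1 holds the lowest CEs and bin `n_bins` the highest.
#'
#' @param records CE records from [compute_ce()].
#' @param n_bins Number of bins (default 4, i.e. quartiles).
#' @return The records with a `bin` column, in bin order.
#' @export
assign_bins <- function(records, n_bins = 4L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  n <- nrow(records)
  if (n < n_bins) stop(sprintf("cannot split %d records into %d bins", n, n_bins))
  o <- ord(records$ce, records$p4rna_id)
  sizes <- n %/% n_bins + (seq_len(n_bins) <= n %% n_bins)
  out <- records[o, , drop = FALSE]
  out$bin <- rep(seq_len(n_bins), sizes)
  rownames(out) <- NULL
  out
}

#' Conversion-efficiency table for a catalog and siRNA library
#'
#' Convenience wrapper: counts anchored siRNAs, computes CE, assigns bins,
#' and joins the precursor sequences for composition analysis.
#'
#' @inheritParams count_anchored_sirnas
#' @inheritParams assign_bins
#' @return Binned CE records with a `sequence` column.
#' @export
ce_table <- function(catalog, sirna_reads, n_bins = 4L,
                     weight = c("full", "fractional"), length_window = NULL) {
  counts <- count_anchored_sirnas(catalog, sirna_reads, weight = weight,
                                  length_window = length_window)
  rec <- assign_bins(compute_ce(counts, catalog), n_bins = n_bins)
  rec$sequence <- catalog$sequence[match(rec$p4rna_id, catalog$id)]
  rec
}

#' Write a CE table as TSV
#'
#' @param records Binned CE records.
#' @param path Output path.
#' @export
write_ce_table <- function(records, path) {
  cols <- intersect(c("p4rna_id", "p4rna_reads", "sirna_reads", "ce", "bin"),
                    names(records))
  write_tsv(records[cols], path)
}
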
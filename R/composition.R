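#' Per-bin nucleotide frequency at a guide position
#'
#' Tallies the nucleotide at position `position` (1 = g1, the 5'
#' nucleotide; 2 = g2) across the P4RNAs of each CE bin. Frequencies are
#' computed over distinct precursor species, unweighted by read counts
#' (figure-style species-level tallies); set `weight_by_reads = TRUE` for a
#' read-weighted sensitivity analysis.
#'
#' @param records Binned CE records with a `sequence` column (see
#'   [ce_table()]).
#' @param position Guide position, 1 or 2.
#' @param weight_by_reads Weight species by `p4rna_reads` instead of
#'   counting each once.
#' @return A `composition_table` data.frame: `bin`, `n`, and frequency
#'   columns `A`, `U`, `C`, `G` summing to 1 per bin.
#' @export
positional_frequency <- function(records, position = 1L, weight_by_reads = FALSE) {
  stopifnot(position %in% c(1L, 2L), "bin" %in% names(records))
  if (any(nchar(records$sequence) < position)) {
    stop("every sequence must reach the requested position")
  }
  nt <- substr(records$sequence, position, position)
  w <- if (weight_by_reads) records$p4rna_reads else rep(1, nrow(records))
  bins <- sort(unique(records$bin))
  rows <- lapply(bins, function(b) {
    i <- records$bin == b
    if (!any(i)) stop(sprintf("bin %d is empty", b))
    tot <- sum(w[i])
    freq <- vapply(BASES_DNA, function(base) sum(w[i][nt[i] == base]) / tot,
                   numeric(1))
    data.frame(bin = b, n = sum(i), A = freq[["A"]], U = freq[["T"]],
               C = freq[["C"]], G = freq[["G"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, position = position, class = c("composition_table", "data.frame"))
}

#' Per-bin g2 stability-class frequencies conditional on the 5' nucleotide
#'
#' Restricts to P4RNAs whose first nucleotide equals `g1_filter`, then per
#' CE bin reports the frequency of a weak (A/U) versus strong (C/G)
#' nucleotide at g2 — a proxy for the thermodynamic stability of the siRNA
#' duplex's 5'-terminal base pair. Bins left empty by the g1 filter are
#' reported with `n = 0` and `NA` frequencies rather than raising.
#'
#' @param records Binned CE records with a `sequence` column.
#' @param g1_filter 5' nucleotide to condition on, one of A/U/C/G (T is
#'   accepted as U).
#' @return A `stability_table` data.frame: `bin`, `n`, `weak`, `strong`.
#' @export
stability_bias <- function(records, g1_filter = "A") {
  g1_filter <- normalize_seq(g1_filter)
  stopifnot(g1_filter %in% BASES_DNA, "bin" %in% names(records))
  if (any(nchar(records$sequence) < 2L)) stop("sequences must be at least 2 nt")
  keep <- substr(records$sequence, 1L, 1L) == g1_filter
  g2 <- substr(records$sequence, 2L, 2L)
  bins <- sort(unique(records$bin))
  rows <- lapply(bins, function(b) {
    i <- records$bin == b & keep
    n <- sum(i)
    if (n == 0L) {
      return(data.frame(bin = b, n = 0L, weak = NA_real_, strong = NA_real_))
    }
    weak <- mean(g2[i] %in% c("A", "T"))
    data.frame(bin = b, n = n, weak = weak, strong = 1 - weak)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, g1_filter = dna_to_rna(g1_filter),
            class = c("stability_table", "data.frame"))
}

#' Frequency trend across CE bins for one nucleotide or stability class
#'
#' Scalar summary of the composition trend: the frequency of `symbol` in
#' the highest bin minus its frequency in the lowest bin (bins with no
#' members after filtering are excluded). Positive values mean the symbol
#' is enriched among efficiently converted precursors.
#'
#' @param table A `composition_table` or `stability_table`.
#' @param symbol A nucleotide (`"A"`, `"U"`, `"C"`, `"G"`) or stability
#'   class (`"weak"`, `"strong"`) present in the table.
#' @return Signed frequency difference (last bin minus first bin).
#' @export
trend_summary <- function(table, symbol) {
  if (!symbol %in% names(table)) {
    stop(sprintf("symbol '%s' not present in the table", symbol))
  }
  tab <- table[table$n > 0L, , drop = FALSE]
  if (nrow(tab) < 2L) stop("need at least 2 non-empty bins for a trend")
  tab[[symbol]][nrow(tab)] - tab[[symbol]][1L]
}

#' Sampling-error bound for a between-bin frequency difference
#'
#' Under a null where bin membership is independent of the tallied symbol,
#' the difference of two bin frequencies has standard error
#' `sqrt(p(1-p)(1/n_first + 1/n_last))` by binomial sampling; the bound is
#' `z` such standard errors.
#'
#' @param n_first,n_last Species counts in the compared bins.
#' @param p Overall symbol frequency.
#' @param z Number of standard errors (default 3).
#' @export
trend_sampling_bound <- function(n_first, n_last, p, z = 3) {
  stopifnot(n_first > 0L, n_last > 0L, p >= 0, p <= 1)
  z * sqrt(p * (1 - p) * (1 / n_first + 1 / n_last))
}

#' Write a composition or stability table as TSV
#'
#' @param table A `composition_table` or `stability_table`.
#' @param path Output path.
#' @export
write_composition <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}
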
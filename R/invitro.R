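#' Normalize band intensities to a reference condition
#'
#' Gel band intensities from in vitro RISC-assembly assays are normalized
#' within each replicate to that replicate's reference condition
#' (canonically the 5' A guide), so the reference is exactly 1 in every
#' replicate. Summaries are the mean and sample SD (n - 1) over replicates.
#'
#' @param measurements data.frame with columns `condition`, `replicate`,
#'   `intensity` (non-negative).
#' @param reference Condition to normalize to; must be present with
#'   positive intensity in every replicate.
#' @return A `relative_efficiency` list with `values` (per-replicate
#'   normalized intensities) and `summary` (condition, mean, sd, n).
#' @export
normalize_to_reference <- function(measurements, reference) {
  check_measurements(measurements)
  reps <- unique(measurements$replicate)
  ref <- measurements[measurements$condition == reference, , drop = FALSE]
  if (!setequal(ref$replicate, reps) || anyDuplicated(ref$replicate)) {
    stop(sprintf("reference condition '%s' must appear exactly once per replicate", reference))
  }
  if (any(ref$intensity <= 0)) {
    stop(sprintf("reference condition '%s' has non-positive intensity", reference))
  }
  denom <- stats::setNames(ref$intensity, ref$replicate)
  values <- measurements
  values$normalized <- values$intensity / denom[as.character(values$replicate)]
  structure(list(values = values,
                 summary = summarize_by_condition(values, "normalized"),
                 reference = reference),
            class = "relative_efficiency")
}

#' Total-normalized intensity distribution per replicate
#'
#' Each condition's intensity is divided by its replicate's total, so the
#' fractions sum to 1 within every replicate (the "total band intensity as
#' 1" convention for length distributions).
#'
#' @inheritParams normalize_to_reference
#' @return A `relative_efficiency`-style list with per-replicate `fraction`
#'   values and a mean/SD summary per condition.
#' @export
total_normalized_distribution <- function(measurements) {
  check_measurements(measurements)
  totals <- tapply(measurements$intensity, measurements$replicate, sum)
  if (any(totals <= 0)) stop("each replicate must have a positive total intensity")
  values <- measurements
  values$fraction <- values$intensity / as.numeric(totals[as.character(values$replicate)])
  structure(list(values = values,
                 summary = summarize_by_condition(values, "fraction")),
            class = "relative_efficiency")
}

check_measurements <- function(measurements) {
  stopifnot(all(c("condition", "replicate", "intensity") %in% names(measurements)))
  if (any(measurements$intensity < 0)) stop("intensities must be non-negative")
  if (anyDuplicated(measurements[c("condition", "replicate")])) {
    stop("duplicated (condition, replicate) measurements")
  }
  invisible(measurements)
}

summarize_by_condition <- function(values, col) {
  conds <- unique(values$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    v <- values[[col]][values$condition == cc]
    data.frame(condition = cc, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.relative_efficiency <- function(x, ...) {
  if (!is.null(x$reference)) {
    cat(sprintf("Relative efficiency (reference = %s):\n", x$reference))
  } else {
    cat("Total-normalized distribution:\n")
  }
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Paired t-tests with Benjamini-Hochberg correction
#'
#' Runs a two-sided paired t-test for each requested condition pair (paired
#' by replicate; pairing must be complete) and adjusts the raw p-values
#' across all non-degenerate comparisons by the Benjamini-Hochberg step-up
#' procedure. Comparisons whose paired differences have zero variance are
#' flagged as degenerate, reported with `NA` p-values, and excluded from
#' the adjustment (with a warning).
#'
#' @param values data.frame with columns `condition`, `replicate`, `value`.
#' @param comparisons List of length-2 character vectors of conditions to
#'   compare.
#' @return data.frame with `comparison`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `degenerate`.
#' @export
paired_t_bh <- function(values, comparisons) {
  stopifnot(all(c("condition", "replicate", "value") %in% names(values)),
            length(comparisons) >= 1L)
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2L)
    a <- values[values$condition == cmp[1], , drop = FALSE]
    b <- values[values$condition == cmp[2], , drop = FALSE]
    a <- a[ord(as.character(a$replicate)), , drop = FALSE]
    b <- b[ord(as.character(b$replicate)), , drop = FALSE]
    if (nrow(a) < 2L || !identical(as.character(a$replicate), as.character(b$replicate))) {
      stop(sprintf("incomplete pairing for comparison %s vs %s", cmp[1], cmp[2]))
    }
    d <- a$value - b$value
    if (stats::sd(d) == 0) {
      return(data.frame(comparison = paste(cmp, collapse = " vs "),
                        statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a$value, b$value, paired = TRUE)
    data.frame(comparison = paste(cmp, collapse = " vs "),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !out$degenerate
  if (any(out$degenerate)) {
    warning(sprintf("%d comparison(s) with zero-variance paired differences excluded from BH adjustment",
                    sum(out$degenerate)))
  }
  if (any(ok)) out$p_adjusted[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  rownames(out) <- NULL
  out[c("comparison", "statistic", "df", "p_value", "p_adjusted", "degenerate")]
}
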
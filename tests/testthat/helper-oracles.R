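# Independent brute-force oracles. These deliberately share no code with
# the package implementation: plain loops and sorts only.

random_seq <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# naive all-window scan: every exact sense-strand occurrence
oracle_map <- function(read_seq, refs) {
  out <- data.frame(reference_id = character(), offset = integer())
  L <- nchar(read_seq)
  for (rid in names(refs)) {
    ref <- refs[[rid]]
    if (nchar(ref) < L) next
    for (s in seq_len(nchar(ref) - L + 1L)) {
      if (substr(ref, s, s + L - 1L) == read_seq) {
        out <- rbind(out, data.frame(reference_id = rid, offset = s - 1L))
      }
    }
  }
  out[order(out$reference_id, out$offset, method = "radix"), , drop = FALSE]
}

# naive CE + contiguous equal split, recounted from scratch
oracle_ce_bins <- function(catalog, sirnas, n_bins) {
  ce <- numeric(nrow(catalog))
  sr <- numeric(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    tot <- 0
    for (j in seq_len(nrow(sirnas))) {
      s <- sirnas$sequence[j]
      if (nchar(s) <= nchar(catalog$sequence[i]) &&
          substr(catalog$sequence[i], 1, nchar(s)) == s) {
        tot <- tot + sirnas$count[j]
      }
    }
    sr[i] <- tot
    ce[i] <- tot / catalog$read_count[i]
  }
  o <- order(ce, catalog$id, method = "radix")
  n <- nrow(catalog)
  sizes <- rep(n %/% n_bins, n_bins)
  if (n %% n_bins > 0) sizes[seq_len(n %% n_bins)] <- sizes[seq_len(n %% n_bins)] + 1L
  data.frame(p4rna_id = catalog$id[o], sirna_reads = sr[o], ce = ce[o],
             bin = rep(seq_len(n_bins), sizes), stringsAsFactors = FALSE)
}

# O(m^2) Benjamini-Hochberg step-up: adj_(k) = min_{j >= k} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    best <- Inf
    for (j in k:m) best <- min(best, ps[j] * m / j)
    adj[k] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# small random catalog + siRNA library for oracle-equivalence checks
random_ce_instance <- function(n_p4 = NULL) {
  if (is.null(n_p4)) n_p4 <- sample(4:50, 1)
  catalog <- data.frame(
    id = sprintf("p4_%05d", seq_len(n_p4)),
    cluster = sprintf("c%02d", seq_len(n_p4)),
    position = 0L, strand = "+",
    sequence = vapply(seq_len(n_p4), function(i) random_seq(sample(31:40, 1)),
                      character(1)),
    stringsAsFactors = FALSE)
  catalog$length <- nchar(catalog$sequence)
  catalog$read_count <- sample(51:500, n_p4, replace = TRUE)
  n_s <- sample(5:60, 1)
  src <- sample(n_p4, n_s, replace = TRUE)
  sirnas <- data.frame(
    sequence = vapply(seq_len(n_s), function(j) {
      if (stats::runif(1) < 0.8) {
        substr(catalog$sequence[src[j]], 1, sample(19:25, 1))  # true prefix
      } else {
        random_seq(sample(19:25, 1))                           # decoy
      }
    }, character(1)),
    count = sample(1:200, n_s, replace = TRUE),
    stringsAsFactors = FALSE)
  list(catalog = catalog, sirnas = sirnas)
}
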
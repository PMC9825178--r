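#' Biogenesis (Pol IV / RDR2 / DCL3) simulation parameters
#'
#' Describes the precursor pool: locus count, precursor length range,
#' +1-nucleotide bias (Pol IV transcription start sites prefer purines),
#' body composition, and a heavy-tailed per-locus abundance model
#' (log-normal locus means with negative-binomial counts, rescaled to the
#' configured sequencing depth by a multinomial draw).
#'
#' @param n_loci Number of precursor loci.
#' @param length_range Inclusive precursor length range (default 31-40 nt,
#'   so the >30 nt catalog filter passes by construction while the read
#'   filter still bites).
#' @param plus_one_weights Probabilities over A/U/C/G for the precursor's
#'   first nucleotide; the default favors A and G.
#' @param body_composition Probabilities over A/U/C/G for positions >= 2;
#'   the default is mildly AT-rich, as in heterochromatic targets.
#' @param abundance_log_mean,abundance_log_sd Log-normal parameters of the
#'   per-locus mean abundance (defaults 0 and 1.2).
#' @param nb_dispersion Negative-binomial dispersion of per-locus counts
#'   around their mean (variance = mu + dispersion * mu^2; default 0.3).
#' @param precursor_depth Total collapsed precursor read count (exact after
#'   the multinomial rescale).
#' @param seed Integer seed for this stage.
#' @export
biogenesis_params <- function(n_loci = 2000L,
                              length_range = c(31L, 40L),
                              plus_one_weights = c(A = 0.45, U = 0.10, C = 0.10, G = 0.35),
                              body_composition = c(A = 0.30, U = 0.30, C = 0.20, G = 0.20),
                              abundance_log_mean = 0,
                              abundance_log_sd = 1.2,
                              nb_dispersion = 0.3,
                              precursor_depth = 5e5,
                              seed = 1L) {
  plus_one_weights <- check_weights(plus_one_weights, "plus_one_weights")
  body_composition <- check_weights(body_composition, "body_composition")
  stopifnot(n_loci >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[1] <= length_range[2],
            abundance_log_sd >= 0, nb_dispersion >= 0, precursor_depth >= 1)
  structure(list(n_loci = as.integer(n_loci),
                 length_range = as.integer(length_range),
                 plus_one_weights = plus_one_weights,
                 body_composition = body_composition,
                 abundance_log_mean = abundance_log_mean,
                 abundance_log_sd = abundance_log_sd,
                 nb_dispersion = nb_dispersion,
                 precursor_depth = precursor_depth,
                 seed = as.integer(seed)),
            class = "biogenesis_params")
}

check_weights <- function(w, what) {
  stopifnot(length(w) == 4L, !is.null(names(w)))
  w <- w[BASES_RNA]
  if (anyNA(w) || any(w < 0)) stop(what, " must be non-negative and named A/U/C/G")
  if (sum(w) <= 0) stop(what, ": all weights are zero")
  w / sum(w)
}

#' Argonaute loading simulation parameters
#'
#' Each candidate guide's sampling weight is its source-locus abundance
#' times a 5'-nucleotide weight, times `g2_stability_weight` when the
#' second nucleotide is A/U (thermodynamically weak 5'-terminal pair),
#' times a guide-length weight. AGO-bound reads are drawn multinomially.
#'
#' @param five_prime_weights Positive weights named A/U/C/G for the guide
#'   5' nucleotide (need not be normalized).
#' @param g2_stability_weight Multiplier applied when g2 is A or U
#'   (default 1 = no terminal-stability preference).
#' @param length_weights Named weights over guide lengths 19-25 nt; the
#'   default peaks at 24 nt, the canonical heterochromatic siRNA length.
#' @param sirna_depth Total AGO-bound read count.
#' @param seed Integer seed for this stage.
#' @export
loading_params <- function(five_prime_weights = c(A = 1, U = 1, C = 1, G = 1),
                           g2_stability_weight = 1,
                           length_weights = c(`19` = 0.02, `20` = 0.05,
                                              `21` = 0.10, `22` = 0.15,
                                              `23` = 0.30, `24` = 1.00,
                                              `25` = 0.30),
                           sirna_depth = 1e5,
                           seed = 1L) {
  stopifnot(length(five_prime_weights) == 4L, !is.null(names(five_prime_weights)))
  five_prime_weights <- five_prime_weights[BASES_RNA]
  if (anyNA(five_prime_weights) || any(five_prime_weights < 0)) {
    stop("five_prime_weights must be non-negative and named A/U/C/G")
  }
  stopifnot(g2_stability_weight > 0, all(length_weights >= 0),
            !is.null(names(length_weights)), sirna_depth >= 1)
  structure(list(five_prime_weights = five_prime_weights,
                 g2_stability_weight = g2_stability_weight,
                 length_weights = length_weights,
                 sirna_depth = sirna_depth,
                 seed = as.integer(seed)),
            class = "loading_params")
}

#' AGO4-like loading preset
#'
#' 5' weights (A=1, U=0.5, C=0.2, G=0.3) follow the measured in vitro
#' relative loading efficiencies of 24-nt siRNAs (~50%, ~20% and ~30% for
#' 5' U/C/G versus 5' A); the terminal-stability multiplier of 2 encodes
#' the additional preference for a weak 5'-terminal pair and is an
#' illustrative choice, not a measured value.
#'
#' @inheritParams loading_params
#' @param ... Passed to [loading_params()].
#' @export
loading_params_ago4 <- function(sirna_depth = 1e5, seed = 1L, ...) {
  loading_params(five_prime_weights = c(A = 1, U = 0.5, C = 0.2, G = 0.3),
                 g2_stability_weight = 2,
                 sirna_depth = sirna_depth, seed = seed, ...)
}

#' AGO6-like loading preset
#'
#' A strict 5'-A caricature (A=1, others 0.05) for an Argonaute that loads
#' almost exclusively 5'-A guides. No quantitative AGO6 weight estimates
#' exist to calibrate against; this preset is qualitative by design.
#'
#' @inheritParams loading_params
#' @param ... Passed to [loading_params()].
#' @export
loading_params_ago6 <- function(sirna_depth = 1e5, seed = 1L, ...) {
  loading_params(five_prime_weights = c(A = 1, U = 0.05, C = 0.05, G = 0.05),
                 g2_stability_weight = 1,
                 sirna_depth = sirna_depth, seed = seed, ...)
}

#' Simulate a pool of Pol IV precursor (P4RNA) species
#'
#' Draws `n_loci` precursor sequences with lengths uniform on the
#' configured range, first nucleotide from the +1 weights and body
#' positions i.i.d. from the body composition; per-locus read counts come
#' from the log-normal/negative-binomial abundance model rescaled to
#' exactly `precursor_depth` total reads by a multinomial draw.
#'
#' @param params A [biogenesis_params()] object.
#' @return data.frame with `locus_id`, `sequence` (DNA alphabet), `length`,
#'   `count` (may be zero for loci that drew no reads).
#' @export
simulate_p4rna_pool <- function(params = biogenesis_params()) {
  stopifnot(inherits(params, "biogenesis_params"))
  set.seed(params$seed)
  n <- params$n_loci
  lens <- sample(seq(params$length_range[1], params$length_range[2]), n, replace = TRUE)
  bases <- chartr("U", "T", BASES_RNA)
  first <- sample(bases, n, replace = TRUE, prob = params$plus_one_weights)
  maxlen <- max(lens)
  body <- matrix(sample(bases, n * (maxlen - 1L), replace = TRUE,
                        prob = params$body_composition),
                 nrow = n)
  seqs <- vapply(seq_len(n), function(i) {
    paste0(first[i], paste(body[i, seq_len(lens[i] - 1L)], collapse = ""))
  }, character(1))
  mu <- stats::rlnorm(n, meanlog = params$abundance_log_mean,
                      sdlog = params$abundance_log_sd)
  # scale locus means to the target depth before drawing counts, so the
  # count scale (and hence the >50-read filter) is depth-dependent
  mu <- mu / sum(mu) * params$precursor_depth
  x <- if (params$nb_dispersion > 0) {
    stats::rnbinom(n, mu = mu, size = 1 / params$nb_dispersion)
  } else {
    stats::rpois(n, mu)
  }
  w <- if (sum(x) > 0) x else mu
  counts <- as.integer(stats::rmultinom(1L, size = params$precursor_depth, prob = w))
  data.frame(locus_id = sprintf("locus_%05d", seq_len(n)),
             sequence = seqs, length = lens, count = counts,
             stringsAsFactors = FALSE)
}

#' 5'-anchored guide prefixes of a precursor
#'
#' Dicing of the precursor-derived duplex is modeled as producing
#' 5'-anchored guides, so guide g1 always equals the precursor's +1
#' nucleotide.
#'
#' @param precursor A single precursor sequence.
#' @param lengths Guide lengths to excise (each must not exceed the
#'   precursor length).
#' @return Character vector of guide sequences, named by length.
#' @export
dice_to_guides <- function(precursor, lengths = 19:25) {
  stopifnot(length(precursor) == 1L)
  precursor <- normalize_seq(precursor)
  if (any(lengths > nchar(precursor))) {
    stop("requested guide length exceeds the precursor length")
  }
  stats::setNames(substr(rep(precursor, length(lengths)), 1L, lengths),
                  as.character(lengths))
}

#' Candidate guide table for a precursor pool
#'
#' Expands every precursor into its 5'-anchored guides at the requested
#' lengths, carrying the source-locus abundance.
#'
#' @param pool Output of [simulate_p4rna_pool()].
#' @param lengths Guide lengths (default 19-25 nt).
#' @return data.frame with `locus_id`, `length`, `sequence`, `abundance`.
#' @export
make_guides <- function(pool, lengths = 19:25) {
  lengths <- sort(as.integer(lengths))
  if (any(lengths > min(nchar(pool$sequence)))) {
    stop("requested guide length exceeds a precursor length")
  }
  n <- nrow(pool)
  k <- length(lengths)
  data.frame(locus_id = rep(pool$locus_id, each = k),
             length = rep(lengths, times = n),
             sequence = substr(rep(pool$sequence, each = k), 1L,
                               rep(lengths, times = n)),
             abundance = rep(pool$count, each = k),
             stringsAsFactors = FALSE)
}

#' Simulate Argonaute loading over candidate guides
#'
#' Each guide's weight is abundance x five_prime_weights[g1] x
#' (g2_stability_weight if g2 is A/U) x length_weights[length];
#' `sirna_depth` reads are drawn multinomially and collapsed by sequence.
#'
#' @param guides Guide table from [make_guides()] (columns `sequence`,
#'   `abundance`, `length`).
#' @param params A [loading_params()] object.
#' @return data.frame of AGO-bound siRNA species: `id`, `sequence`,
#'   `count` (only species with positive counts).
#' @export
simulate_loading <- function(guides, params = loading_params()) {
  stopifnot(inherits(params, "loading_params"))
  w5 <- params$five_prime_weights
  names(w5) <- chartr("U", "T", names(w5))
  g1 <- substr(guides$sequence, 1L, 1L)
  g2 <- substr(guides$sequence, 2L, 2L)
  lw <- params$length_weights[as.character(guides$length)]
  if (anyNA(lw)) stop("guide lengths outside length_weights")
  w <- guides$abundance * w5[g1] *
    ifelse(g2 %in% c("A", "T"), params$g2_stability_weight, 1) *
    as.numeric(lw)
  if (all(w == 0)) stop("all guide weights are zero")
  set.seed(params$seed)
  draws <- as.numeric(stats::rmultinom(1L, size = params$sirna_depth, prob = w))
  pos <- draws > 0
  agg <- rowsum(draws[pos], group = guides$sequence[pos])
  out <- data.frame(sequence = rownames(agg), count = as.integer(agg[, 1L]),
                    stringsAsFactors = FALSE)
  out <- out[ord(out$sequence), , drop = FALSE]
  out <- cbind(id = sprintf("sirna_%05d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic dataset (precursors, siRNAs, clusters)
#'
#' Runs the biogenesis and loading models and assembles everything the
#' analysis pipeline consumes: collapsed precursor reads, collapsed
#' AGO-bound siRNA reads, one cluster reference per locus (the precursor
#' embedded between random flanks, so mapping and anchoring are exercised
#' non-trivially), and the ground truth (parameters plus true anchors).
#' With `dir` set, writes precursor/siRNA FASTA, cluster BED + genome
#' FASTA, and a ground-truth JSON; identical seeds give byte-identical
#' files.
#'
#' @param bio A [biogenesis_params()] object.
#' @param load A [loading_params()] object.
#' @param dir Optional output directory (created if needed).
#' @param guide_lengths Guide lengths offered to loading (default 19-25).
#' @param flank Flank width added on each side of a precursor to form its
#'   cluster reference (default 10 nt).
#' @return A `synthetic_dataset` list: `precursors`, `sirnas` (read
#'   tables), `clusters` (a [reference_set()]), `anchors`, `ground_truth`,
#'   and `files` when written.
#' @export
make_dataset <- function(bio = biogenesis_params(), load = loading_params(),
                         dir = NULL, guide_lengths = 19:25, flank = 10L) {
  pool <- simulate_p4rna_pool(bio)
  guides <- make_guides(pool, lengths = guide_lengths)
  sirnas <- simulate_loading(guides, load)

  # cluster scaffolds: flank5 + precursor + flank3, flanks from body composition
  set.seed(derive_seeds(bio$seed, 2L)[2L])
  bases <- chartr("U", "T", BASES_RNA)
  n <- nrow(pool)
  fl <- matrix(sample(bases, n * 2L * flank, replace = TRUE,
                      prob = bio$body_composition), nrow = n)
  left <- apply(fl[, seq_len(flank), drop = FALSE], 1L, paste, collapse = "")
  right <- apply(fl[, flank + seq_len(flank), drop = FALSE], 1L, paste, collapse = "")
  cluster_ids <- sprintf("cluster_%05d", seq_len(n))
  clusters <- reference_set(
    stats::setNames(paste0(left, pool$sequence, right), cluster_ids),
    kind = "cluster")
  anchors <- data.frame(locus_id = pool$locus_id, cluster = cluster_ids,
                        position = as.integer(flank), strand = "+",
                        stringsAsFactors = FALSE)

  pos <- pool$count > 0L
  precursors <- data.frame(id = sprintf("p4read_%05d", seq_len(sum(pos))),
                           sequence = pool$sequence[pos],
                           count = pool$count[pos],
                           stringsAsFactors = FALSE)
  ds <- structure(list(precursors = precursors, sirnas = sirnas,
                       clusters = clusters, anchors = anchors, pool = pool,
                       ground_truth = list(biogenesis = unclass(bio),
                                           loading = unclass(load),
                                           anchors = anchors)),
                  class = "synthetic_dataset")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(precursor_fasta = file.path(dir, "precursors.fasta"),
                  sirna_fasta = file.path(dir, "sirnas.fasta"),
                  clusters_bed = file.path(dir, "clusters.bed"),
                  genome_fasta = file.path(dir, "clusters.fasta"),
                  ground_truth = file.path(dir, "ground_truth.json"))
    write_small_rna(precursors, files$precursor_fasta)
    write_small_rna(sirnas, files$sirna_fasta)
    ss <- Biostrings::DNAStringSet(clusters$entries)
    Biostrings::writeXStringSet(ss, files$genome_fasta)
    bed <- GenomicRanges::GRanges(
      seqnames = cluster_ids,
      ranges = IRanges::IRanges(start = 1L, width = nchar(clusters$entries)),
      strand = "+")
    bed$name <- cluster_ids
    rtracklayer::export(bed, files$clusters_bed, format = "BED")
    jsonlite::write_json(ds$ground_truth, files$ground_truth,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ds$files <- files
  }
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d loci (%d with reads, depth %d), %d siRNA species (depth %d)>\n",
              nrow(x$pool), nrow(x$precursors), sum(x$precursors$count),
              nrow(x$sirnas), sum(x$sirnas$count)))
  invisible(x)
}
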
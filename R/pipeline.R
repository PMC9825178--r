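#' Pipeline configuration
#'
#' Either point at input files (`precursor_fasta`, `sirna_fasta`, and
#' clusters as `clusters_bed` + `genome_fasta` or a pre-extracted
#' `clusters_fasta`) or supply simulation parameter records (`bio`,
#' `load`) to generate the inputs in place.
#'
#' @param precursor_fasta,sirna_fasta Collapsed read files (FASTA/FASTQ).
#' @param clusters_bed,genome_fasta BED intervals plus genome to slice
#'   cluster sequences from.
#' @param clusters_fasta Alternatively, cluster sequences directly.
#' @param bio,load Simulation parameters ([biogenesis_params()],
#'   [loading_params()]); used when no input files are given.
#' @param adapter,min_overlap,min_length 3'-adapter trimming settings.
#' @param params Catalog filters ([catalog_params()]).
#' @param n_bins Number of CE bins (default 4).
#' @param g1_filters 5' nucleotides for the g2 stability analysis
#'   (default A and G).
#' @param out_dir Output directory.
#' @param log_level One of debug/info/warn/error/quiet.
#' @export
pipeline_config <- function(precursor_fasta = NULL, sirna_fasta = NULL,
                            clusters_bed = NULL, genome_fasta = NULL,
                            clusters_fasta = NULL,
                            bio = NULL, load = NULL,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_overlap = 8L, min_length = 15L,
                            params = catalog_params(), n_bins = 4L,
                            g1_filters = c("A", "G"),
                            out_dir = tempfile("p4ce_run_"),
                            log_level = "info") {
  simulate <- is.null(precursor_fasta)
  if (simulate) {
    if (is.null(bio)) bio <- biogenesis_params()
    if (is.null(load)) load <- loading_params()
  } else {
    for (p in c(precursor_fasta, sirna_fasta, clusters_bed, genome_fasta, clusters_fasta)) {
      if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
    }
    if (is.null(sirna_fasta)) stop("sirna_fasta is required with file inputs")
    if (is.null(clusters_fasta) && (is.null(clusters_bed) || is.null(genome_fasta))) {
      stop("provide clusters_fasta, or clusters_bed plus genome_fasta")
    }
  }
  stopifnot(n_bins >= 1L)
  structure(list(simulate = simulate,
                 precursor_fasta = precursor_fasta, sirna_fasta = sirna_fasta,
                 clusters_bed = clusters_bed, genome_fasta = genome_fasta,
                 clusters_fasta = clusters_fasta,
                 bio = bio, load = load,
                 adapter = adapter, min_overlap = min_overlap,
                 min_length = min_length,
                 params = params, n_bins = as.integer(n_bins),
                 g1_filters = g1_filters,
                 out_dir = out_dir, log_level = log_level),
            class = "pipeline_config")
}

#' Run the full analysis on an in-memory dataset
#'
#' Trims adapters, maps precursor reads to cluster references, builds and
#' filters the P4RNA catalog, computes CE against the siRNA library,
#' assigns bins, and profiles g1 composition and g2 stability.
#'
#' @param precursors,sirnas Collapsed read tables (`id`, `sequence`,
#'   `count`).
#' @param clusters Cluster [reference_set()].
#' @param config A [pipeline_config()] (trimming/filter/binning settings).
#' @return List with `catalog`, `records` (binned CE table with
#'   sequences), `g1_composition`, `stability` (one table per g1 filter),
#'   `trends`, and `counts` (stage-by-stage audit numbers).
#' @export
analyze_dataset <- function(precursors, sirnas, clusters,
                            config = pipeline_config()) {
  counts <- list(precursor_species_in = nrow(precursors),
                 precursor_reads_in = sum(precursors$count),
                 sirna_species_in = nrow(sirnas),
                 sirna_reads_in = sum(sirnas$count))
  pre <- trim_reads(precursors, adapter = config$adapter,
                    min_overlap = config$min_overlap,
                    min_length = config$min_length)
  sir <- trim_reads(sirnas, adapter = config$adapter,
                    min_overlap = config$min_overlap,
                    min_length = config$min_length)
  counts$precursor_species_after_trim <- nrow(pre)
  counts$sirna_species_after_trim <- nrow(sir)

  hits <- map_to_references(pre, clusters)
  counts$precursor_species_mapped <- length(unique(hits$read_id))
  raw_catalog <- collapse_by_five_prime(pre, hits)
  counts$species_pre_filter <- nrow(raw_catalog)
  catalog <- filter_catalog(raw_catalog, config$params)
  counts$species_post_filter <- nrow(catalog)
  if (nrow(catalog) < config$n_bins) {
    stop(sprintf("catalog stage: only %d species survive filtering; need >= %d for binning",
                 nrow(catalog), config$n_bins))
  }
  records <- ce_table(catalog, sir, n_bins = config$n_bins)
  counts$per_bin_n <- as.list(stats::setNames(
    as.integer(table(records$bin)), paste0("bin", sort(unique(records$bin)))))

  g1 <- positional_frequency(records, position = 1L)
  stability <- lapply(stats::setNames(config$g1_filters, config$g1_filters),
                      function(nt) stability_bias(records, g1_filter = nt))
  trends <- if (config$n_bins >= 2L) {
    tr <- c(list(trend_summary(g1, "A")),
            lapply(stability, function(s) trend_summary(s, "weak")))
    stats::setNames(tr, c("g1_A", paste0("g2_weak_given_5p", config$g1_filters)))
  } else {
    list()  # a trend needs at least two bins
  }
  list(catalog = catalog, records = records, g1_composition = g1,
       stability = stability, trends = trends, counts = counts)
}

#' Run the pipeline end to end and write all outputs
#'
#' Loads (or simulates) the inputs, runs [analyze_dataset()], writes the
#' catalog, CE table, composition and stability TSVs plus a machine-
#' readable JSON report of stage counts and trend summaries. Identical
#' configuration (including seeds) gives identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run report (invisibly), as written to
#'   `<out_dir>/report.json`.
#' @export
run_end_to_end <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  op <- options(p4ce.log_level = config$log_level); on.exit(options(op))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$simulate) {
    log_msg("info", "simulating dataset (", config$bio$n_loci, " loci)")
    ds <- make_dataset(config$bio, config$load, dir = file.path(config$out_dir, "sim"))
    precursors <- ds$precursors; sirnas <- ds$sirnas; clusters <- ds$clusters
  } else {
    log_msg("info", "reading inputs")
    precursors <- read_small_rna(config$precursor_fasta)
    sirnas <- read_small_rna(config$sirna_fasta)
    clusters <- if (!is.null(config$clusters_fasta)) {
      read_reference_fasta(config$clusters_fasta, kind = "cluster")
    } else {
      clusters_from_bed(config$clusters_bed, config$genome_fasta)
    }
  }

  log_msg("info", "catalog / CE / composition")
  res <- analyze_dataset(precursors, sirnas, clusters, config)

  files <- list(catalog = file.path(config$out_dir, "catalog.tsv"),
                catalog_fasta = file.path(config$out_dir, "catalog.fasta"),
                ce = file.path(config$out_dir, "ce_table.tsv"),
                g1_composition = file.path(config$out_dir, "g1_composition.tsv"))
  write_catalog(res$catalog, files$catalog, files$catalog_fasta)
  write_ce_table(res$records, files$ce)
  write_composition(res$g1_composition, files$g1_composition)
  for (nt in names(res$stability)) {
    f <- file.path(config$out_dir, sprintf("g2_stability_5p%s.tsv", nt))
    write_composition(res$stability[[nt]], f)
    files[[paste0("stability_5p", nt)]] <- f
  }

  report <- list(counts = res$counts, trends = res$trends,
                 n_bins = config$n_bins, files = files)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("info", "done: ", config$out_dir)
  invisible(report)
}
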
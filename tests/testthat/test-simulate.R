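test_that("precursor pool respects lengths, depth, and +1 weights", {
  pool <- simulate_p4rna_pool(biogenesis_params(n_loci = 100, precursor_depth = 1e4,
                                                seed = 3))
  expect_equal(nrow(pool), 100L)
  expect_true(all(nchar(pool$sequence) >= 31 & nchar(pool$sequence) <= 40))
  expect_equal(sum(pool$count), 1e4)

  # degenerate +1 weights force the first nucleotide
  onlyA <- simulate_p4rna_pool(biogenesis_params(
    n_loci = 50, plus_one_weights = c(A = 1, U = 0, C = 0, G = 0),
    precursor_depth = 1e3, seed = 4))
  expect_true(all(substr(onlyA$sequence, 1, 1) == "A"))

  expect_error(biogenesis_params(plus_one_weights = c(A = 0, U = 0, C = 0, G = 0)),
               "zero")
})

test_that("empirical +1 A fraction sits within 3 binomial SEs of its weight", {
  p <- 0.5
  pool <- simulate_p4rna_pool(biogenesis_params(
    n_loci = 5000, plus_one_weights = c(A = 0.5, U = 0.05, C = 0.05, G = 0.4),
    precursor_depth = 5e4, seed = 8))
  frac <- mean(substr(pool$sequence, 1, 1) == "A")
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 5000))
})

test_that("dicing returns 5'-anchored prefixes with g1 equal to the +1 nucleotide", {
  pre <- random_seq(38)
  g <- dice_to_guides(pre, 24)
  expect_identical(unname(g), substr(pre, 1, 24))
  g_all <- dice_to_guides(pre, 19:25)
  expect_true(all(substr(g_all, 1, 1) == substr(pre, 1, 1)))
  expect_error(dice_to_guides(pre, 40), "exceeds")
})

test_that("loading respects degenerate 5' weights and g2 stability ratios", {
  pool <- simulate_p4rna_pool(biogenesis_params(n_loci = 400, precursor_depth = 4e4,
                                                seed = 21))
  guides <- make_guides(pool)
  sir <- simulate_loading(guides, loading_params(
    five_prime_weights = c(A = 1, U = 0, C = 0, G = 0),
    sirna_depth = 5e3, seed = 22))
  expect_true(all(substr(sir$sequence, 1, 1) == "A"))
  expect_equal(sum(sir$count), 5e3)

  # two otherwise-identical guides differing only at g2 (A vs C), weight 2
  guides2 <- data.frame(locus_id = c("l1", "l2"), length = 24L,
                        sequence = c(paste0("GA", random_seq(22)), NA),
                        abundance = 100L, stringsAsFactors = FALSE)
  guides2$sequence[2] <- paste0("GC", substr(guides2$sequence[1], 3, 24))
  sir2 <- simulate_loading(guides2, loading_params(g2_stability_weight = 2,
                                                   sirna_depth = 3e4, seed = 23))
  frac_weak <- sir2$count[substr(sir2$sequence, 2, 2) == "A"] / sum(sir2$count)
  p <- 2 / 3
  expect_lt(abs(frac_weak - p), 3 * sqrt(p * (1 - p) / 3e4))

  guides2$abundance <- 0L
  expect_error(simulate_loading(guides2, loading_params(sirna_depth = 10)), "zero")
})

test_that("datasets are reproducible and internally consistent", {
  bio <- biogenesis_params(n_loci = 60, precursor_depth = 5e3, seed = 31)
  load <- loading_params(sirna_depth = 500, seed = 32)
  d1 <- tempfile("sim1_"); d2 <- tempfile("sim2_")
  ds1 <- make_dataset(bio, load, dir = d1)
  ds2 <- make_dataset(bio, load, dir = d2)
  for (f in names(ds1$files)) {
    expect_identical(readLines(ds1$files[[f]]), readLines(ds2$files[[f]]),
                     info = f)
  }
  expect_equal(sum(ds1$precursors$count), bio$precursor_depth)
  expect_equal(sum(ds1$sirnas$count), load$sirna_depth)

  # every siRNA is a 5'-anchored prefix of some precursor
  prefix_of_any <- vapply(ds1$sirnas$sequence, function(s) {
    any(substr(ds1$precursors$sequence, 1, nchar(s)) == s)
  }, logical(1))
  expect_true(all(prefix_of_any))

  # anchors: each precursor occurs in its cluster at the stated position
  m <- match(ds1$anchors$cluster, names(ds1$clusters$entries))
  pool_seq <- ds1$pool$sequence
  at_anchor <- substr(ds1$clusters$entries[m], ds1$anchors$position + 1,
                      ds1$anchors$position + nchar(pool_seq)) == pool_seq
  expect_true(all(at_anchor))
})

test_that("file-based and in-memory pipelines agree on a simulated dataset", {
  bio <- biogenesis_params(n_loci = 80, precursor_depth = 1e4, seed = 41)
  load <- loading_params_ago4(sirna_depth = 2e3, seed = 42)
  dir <- tempfile("sim_")
  ds <- make_dataset(bio, load, dir = dir)
  catalog_mem <- build_catalog(ds$precursors, ds$clusters)
  reads <- read_small_rna(ds$files$precursor_fasta)
  clusters <- clusters_from_bed(ds$files$clusters_bed, ds$files$genome_fasta)
  catalog_file <- build_catalog(reads, clusters)
  expect_equal(catalog_file$sequence, catalog_mem$sequence)
  expect_equal(catalog_file$read_count, catalog_mem$read_count)
})
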
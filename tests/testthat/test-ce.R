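toy_catalog <- function(seqs, counts) {
  data.frame(id = sprintf("p4_%05d", seq_along(seqs)),
             cluster = sprintf("c%d", seq_along(seqs)), position = 0L,
             strand = "+", length = nchar(seqs), read_count = counts,
             sequence = seqs, stringsAsFactors = FALSE)
}

test_that("siRNA counting requires 5'-anchored exact prefixes", {
  p1 <- random_seq(32)
  catalog <- toy_catalog(p1, 100L)

  hit <- data.frame(sequence = substr(p1, 1, 24), count = 10L)
  expect_equal(unname(count_anchored_sirnas(catalog, hit)), 10)

  # interior match (offset 3) does not count
  interior <- data.frame(sequence = substr(p1, 4, 27), count = 10L)
  expect_equal(unname(count_anchored_sirnas(catalog, interior)), 0)

  # mismatch anywhere kills the hit
  mm <- substr(p1, 1, 24)
  substr(mm, 12, 12) <- setdiff(c("A", "C", "G", "T"), substr(mm, 12, 12))[1]
  expect_equal(unname(count_anchored_sirnas(catalog, data.frame(sequence = mm, count = 5L))), 0)
})

test_that("multi-mapping siRNAs count fully to every match, or fractionally on request", {
  shared <- random_seq(24)
  catalog <- toy_catalog(c(paste0(shared, random_seq(8)),
                           paste0(shared, random_seq(10))), c(100L, 200L))
  sir <- data.frame(sequence = shared, count = 7L)
  expect_equal(unname(count_anchored_sirnas(catalog, sir)), c(7, 7))
  expect_equal(unname(count_anchored_sirnas(catalog, sir, weight = "fractional")),
               c(3.5, 3.5))
})

test_that("length windows restrict which siRNA reads are counted", {
  p1 <- random_seq(36)
  catalog <- toy_catalog(p1, 80L)
  sir <- data.frame(sequence = c(substr(p1, 1, 21), substr(p1, 1, 24)),
                    count = c(5L, 9L))
  expect_equal(unname(count_anchored_sirnas(catalog, sir)), 14)
  expect_equal(unname(count_anchored_sirnas(catalog, sir, length_window = 23:25)), 9)
})

test_that("CE is the exact read ratio, zero-siRNA entries included", {
  catalog <- toy_catalog(c(random_seq(33), random_seq(34), random_seq(35)),
                         c(200L, 70L, 90L))
  counts <- c(100, 35, 0)
  names(counts) <- catalog$id
  rec <- compute_ce(counts, catalog)
  expect_equal(rec$ce, c(0.5, 0.5, 0))
  expect_equal(nrow(rec), 3L)

  bad <- catalog; bad$read_count[1] <- 0L
  expect_error(compute_ce(counts, bad), "positive")
})

test_that("CE scales linearly in siRNA reads and is ratio-invariant", {
  catalog <- toy_catalog(random_seq(32), 120L)
  sir <- data.frame(sequence = substr(catalog$sequence, 1, 24), count = 30L)
  ce1 <- compute_ce(count_anchored_sirnas(catalog, sir), catalog)$ce
  sir$count <- 90L
  expect_equal(compute_ce(count_anchored_sirnas(catalog, sir), catalog)$ce, 3 * ce1)
  catalog$read_count <- catalog$read_count * 3L
  expect_equal(compute_ce(count_anchored_sirnas(catalog, sir), catalog)$ce, ce1)
})

test_that("bin assignment splits evenly with the remainder in the lowest bins", {
  rec <- data.frame(p4rna_id = sprintf("p%02d", 1:8), p4rna_reads = 100L,
                    sirna_reads = 1:8, ce = (1:8) / 100)
  b <- assign_bins(rec, 4)
  expect_equal(as.integer(table(b$bin)), rep(2L, 4))
  expect_equal(b$bin[order(b$ce)], rep(1:4, each = 2))

  rec10 <- data.frame(p4rna_id = sprintf("p%02d", 1:10), p4rna_reads = 100L,
                      sirna_reads = 1:10, ce = (1:10) / 100)
  expect_equal(as.integer(table(assign_bins(rec10, 4)$bin)), c(3L, 3L, 2L, 2L))

  expect_error(assign_bins(rec[1:3, ], 4), "bins")
})

test_that("tied CEs are split deterministically by id and bins stay ordered", {
  rec <- data.frame(p4rna_id = sprintf("p%02d", sample(1:11)), p4rna_reads = 100L,
                    sirna_reads = 5L, ce = 0.05)
  b <- assign_bins(rec, 4)
  expect_equal(as.integer(table(b$bin)), c(3L, 3L, 3L, 2L))
  # membership fixed by id order under full ties
  expect_equal(b$p4rna_id, sort(rec$p4rna_id, method = "radix"))
  # non-decreasing CE across bin boundaries
  set.seed(99)
  rec$ce <- sample(c(0, 0.1, 0.1, 0.5), 11, replace = TRUE)
  b <- assign_bins(rec, 3)
  for (k in 1:2) {
    expect_lte(max(b$ce[b$bin == k]), min(b$ce[b$bin == k + 1]))
  }
})

test_that("CE pipeline matches the brute-force recount-and-sort oracle", {
  set.seed(2024)
  for (rep in 1:25) {
    inst <- random_ce_instance()
    got <- ce_table(inst$catalog, inst$sirnas, n_bins = 4)
    want <- oracle_ce_bins(inst$catalog, inst$sirnas, 4)
    expect_equal(got$p4rna_id, want$p4rna_id)
    expect_equal(got$sirna_reads, want$sirna_reads)
    expect_equal(got$ce, want$ce)
    expect_equal(got$bin, want$bin)
  }
})
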
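test_that("adapter trimming removes exact and partial 3' adapter matches", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGT"

  # full 12-nt adapter prefix at the 3' end
  tr <- trim_adapter(paste0(insert, substr(adapter, 1, 12)), adapter)
  expect_identical(tr$sequence, insert)
  expect_true(tr$trimmed)

  # no adapter: unchanged
  tr <- trim_adapter(insert, adapter)
  expect_identical(tr$sequence, insert)
  expect_false(tr$trimmed)

  # overlap below the threshold: unchanged
  tr <- trim_adapter(paste0(insert, substr(adapter, 1, 5)), adapter, min_overlap = 8)
  expect_false(tr$trimmed)

  # full adapter inside the read: everything 3' of it goes too
  tr <- trim_adapter(paste0(insert, adapter, "CCCC"), adapter)
  expect_identical(tr$sequence, insert)
  expect_true(tr$trimmed)
})

test_that("adapter trimming is idempotent and batch trimming drops short survivors", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  set.seed(41)
  reads <- vapply(1:60, function(i) {
    ins <- random_seq(sample(10:30, 1))
    if (i %% 2 == 0) paste0(ins, substr(adapter, 1, sample(8:21, 1))) else ins
  }, character(1))
  once <- trim_adapter(reads, adapter)
  twice <- trim_adapter(once$sequence, adapter)
  expect_identical(once$sequence, twice$sequence)

  df <- data.frame(id = sprintf("r%d", seq_along(reads)), sequence = reads,
                   count = 1L)
  kept <- trim_reads(df, adapter, min_length = 15)
  expect_true(all(!kept$trimmed | nchar(kept$sequence) >= 15))
  expect_identical(nrow(df) - nrow(kept), attr(kept, "discarded"))
})

test_that("exact mapping agrees with a naive all-window oracle and with Biostrings", {
  refs <- c(R1 = "TTACGTT", R2 = "ACGTTT")
  hits <- map_to_references("ACGT", reference_set(refs))
  expect_equal(hits$reference_id, c("R1", "R2"))
  expect_equal(hits$offset, c(2L, 0L))
  expect_equal(hits$anchored, c(FALSE, TRUE))

  # occurrences repeated within one reference
  hits <- map_to_references("ACGT", reference_set(c(R1 = "ACGTACGT")))
  expect_equal(hits$offset, c(0L, 4L))

  # read longer than every reference
  expect_equal(nrow(map_to_references(random_seq(50),
                                      reference_set(c(R1 = "ACGTACGT")))), 0L)

  set.seed(7)
  for (rep in 1:20) {
    refs <- stats::setNames(
      vapply(1:8, function(i) random_seq(sample(20:100, 1), c("A", "C")),
             character(1)),
      sprintf("ref%02d", 1:8))
    rs <- reference_set(refs)
    q <- random_seq(sample(3:6, 1), c("A", "C"))
    got <- map_to_references(q, rs)
    want <- oracle_map(q, as.list(refs))
    expect_equal(got$reference_id, want$reference_id)
    expect_equal(got$offset, want$offset)
    # independent cross-check via Biostrings
    bio <- sum(vapply(refs, function(r) {
      length(Biostrings::matchPattern(q, Biostrings::DNAString(r)))
    }, numeric(1)))
    expect_equal(nrow(got), bio)
  }
})

test_that("anchored filter keeps exactly the offset-zero hits", {
  hits <- data.frame(read_id = "r", reference_id = c("a", "a", "b"),
                     offset = c(0L, 4L, 2L), anchored = c(TRUE, FALSE, FALSE))
  kept <- anchored_filter(hits)
  expect_equal(nrow(kept), 1L)
  expect_true(all(kept$offset == 0L))
  expect_equal(nrow(anchored_filter(hits[hits$offset > 0, ])), 0L)
  all0 <- hits[hits$offset == 0, ]
  expect_equal(anchored_filter(all0), all0, ignore_attr = TRUE)
})

test_that("FASTA/FASTQ readers parse collapsed counts and reject bad alphabets", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1_x25", "ACGUACGU",
               ">s2", "acgtacgt",
               ">bad_x3", "ACGTNNN"), fa)
  expect_warning(reads <- read_small_rna(fa), "rejected 1")
  expect_equal(reads$count, c(25L, 1L))
  expect_equal(reads$sequence, c("ACGTACGT", "ACGTACGT"))  # U and case normalized

  # round trip through the collapsed-FASTA writer
  out <- tempfile(fileext = ".fasta")
  write_small_rna(reads, out)
  back <- read_small_rna(out)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$count, reads$count)

  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1_x7", "ACGTA", "+", "IIIII"), fq)
  reads <- read_small_rna(fq)
  expect_equal(reads$count, 7L)
})

test_that("cluster sequences are sliced from BED intervals 0-based half-open", {
  genome <- tempfile(fileext = ".fasta")
  writeLines(c(">chr1", "AACCGGTTAACCGGTT"), genome)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t2\t8\tclusterA\t0\t+", bed)
  rs <- clusters_from_bed(bed, genome)
  expect_identical(unname(rs$entries["clusterA"]), "CCGGTT")
  expect_identical(rs$kind, "cluster")
})
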
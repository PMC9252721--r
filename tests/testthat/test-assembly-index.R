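test_that("a small index holds the expected keys, counts and locations", {
  idx <- build_index(c(c1 = "ACGTACGT"), k = 4)
  info <- index_stats(idx)
  expect_equal(info$n_distinct, 4)
  expect_equal(info$n_windows, 5)
  q <- exact_query(idx, "ACGT")
  expect_equal(q$count, 2L)
  expect_equal(q$locations$offset, c(0, 4))
  expect_equal(q$locations$strand, c("+", "+"))
  for (kmer in c("CGTA", "GTAC", "TACG")) {
    expect_equal(exact_query(idx, kmer)$count, 1L)
  }
  expect_equal(exact_query(idx, "AAAA"), list(
    count = 0L,
    locations = data.frame(contig = character(0), offset = numeric(0),
                           strand = character(0), stringsAsFactors = FALSE)))
})

test_that("windows containing non-ACGT bases are not indexed", {
  idx <- build_index(c(c1 = "ACGNACGT"), k = 3)
  expect_equal(exact_query(idx, "ACG")$count, 2L)
  expect_equal(exact_query(idx, "CGT")$count, 1L)
  expect_equal(index_stats(idx)$n_windows, 3)
})

test_that("multiple contigs index independently with correct ordinals", {
  idx <- build_index(c(c1 = "AAAA", c2 = "AAAA"), k = 4)
  q <- exact_query(idx, "AAAA")
  expect_equal(q$count, 2L)
  expect_equal(q$locations$contig, c("c1", "c2"))
  expect_equal(q$locations$offset, c(0, 0))
  expect_error(build_index(c(c1 = "AAAA", c1 = "CCCC"), k = 4),
               class = "fibkmer_duplicate_contig")
  expect_error(build_index(character(0), k = 4), class = "fibkmer_empty_input")
})

test_that("strand_mode both reports reverse-complement hits with strand '-'", {
  idx <- build_index(c(c1 = "TACG"), k = 4, strand_mode = "both")
  q <- exact_query(idx, "CGTA") # revcomp("TACG")
  expect_equal(q$count, 1L)
  expect_equal(q$locations$strand, "-")
  expect_equal(q$locations$offset, 0)
  # forward hits still reported as '+'
  expect_equal(exact_query(idx, "TACG")$locations$strand, "+")
  # a palindromic k-mer is not double-counted
  idx2 <- build_index(c(c1 = "ACGT"), k = 4, strand_mode = "both")
  expect_equal(exact_query(idx2, "ACGT")$count, 1L)
})

test_that("FASTA files (plain and gzipped, wrapped, soft-masked) are ingested", {
  g <- simulate_genome(31, lengths = c(300, 200))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1 description text",
               tolower(substr(g$contigs[[1]], 1, 150)), # soft-masked chunk
               substr(g$contigs[[1]], 151, 300),
               ">c2", substr(g$contigs[[2]], 1, 80), substr(g$contigs[[2]], 81, 200)),
             fa)
  idx <- build_index(fa, k = 11)
  expect_equal(idx$contigs$name, c("c1", "c2"))
  expect_equal(index_stats(idx)$n_windows, (300 - 10) + (200 - 10))
  fagz <- tempfile(fileext = ".fa.gz")
  write_fasta(g, fagz)
  idx2 <- build_index(fagz, k = 11)
  expect_equal(index_stats(idx2)$n_windows, index_stats(idx)$n_windows)
})

test_that("window counts are conserved and locations decode back to their key", {
  set.seed(32)
  for (seed in 1:5) {
    g <- simulate_genome(seed, lengths = sample(1000:5000, 2))
    for (k in c(5L, 11L, 25L, 31L)) {
      idx <- build_index(g, k = k)
      expect_equal(index_stats(idx)$n_windows,
                   sum(pmax(0, nchar(g$contigs) - k + 1)))
      # every reported location's window re-encodes to the queried k-mer
      for (rep in 1:10) {
        ci <- sample(length(g$contigs), 1)
        off <- sample(nchar(g$contigs[[ci]]) - k + 1, 1) - 1
        kmer <- substr(g$contigs[[ci]], off + 1, off + k)
        q <- exact_query(idx, kmer)
        expect_gte(q$count, 1L)
        for (j in seq_len(q$count)) {
          win <- substr(g$contigs[[q$locations$contig[j]]],
                        q$locations$offset[j] + 1, q$locations$offset[j] + k)
          expect_identical(win, kmer)
        }
      }
    }
  }
})

test_that("exact queries agree with the naive scan oracle", {
  g <- simulate_genome(33, lengths = 4000, n_repeats = 4, repeat_k = 11, repeat_d = 1)
  idx <- build_index(g, k = 11)
  set.seed(33)
  for (rep in 1:100) {
    q <- if (rep %% 2) {
      off <- sample(4000 - 11, 1)
      substr(g$contigs[[1]], off, off + 10)
    } else {
      random_kmer(11)
    }
    naive <- naive_fuzzy_scan(g, q, 0)
    res <- exact_query(idx, q)
    expect_equal(res$count, nrow(naive))
    expect_equal(sort(res$locations$offset), sort(naive$offset))
  }
})

test_that("the index survives a save/load round trip with identical answers", {
  g <- simulate_genome(34, lengths = 2000, n_repeats = 2, repeat_k = 8, repeat_d = 1:2)
  idx <- build_index(g, k = 8)
  path <- tempfile(fileext = ".kmky")
  save_index(idx, path)
  idx2 <- load_index(path)
  expect_equal(idx2$contigs, idx$contigs)
  set.seed(34)
  for (rep in 1:200) {
    q <- random_kmer(8)
    expect_identical(exact_query(idx2, q), exact_query(idx, q))
  }
  # exhaustive over all 4-mers for a tiny index
  small <- build_index(c(c1 = "ACGTACGT"), k = 4)
  p2 <- tempfile()
  save_index(small, p2)
  small2 <- load_index(p2)
  for (code in 0:255) {
    expect_identical(exact_query(small2, code), exact_query(small, code))
  }
})

test_that("corrupt index files are rejected with classed errors", {
  idx <- build_index(c(c1 = "ACGTACGT"), k = 4)
  path <- tempfile()
  save_index(idx, path)
  bytes <- readBin(path, "raw", file.size(path))
  # truncation
  trunc_path <- tempfile()
  writeBin(bytes[1:20], trunc_path)
  expect_error(load_index(trunc_path), class = "fibkmer_format_error")
  # bad magic
  bad <- bytes; bad[1] <- as.raw(0x58)
  bad_path <- tempfile()
  writeBin(bad, bad_path)
  expect_error(load_index(bad_path), class = "fibkmer_format_error")
  # bad version
  bad2 <- bytes; bad2[5] <- as.raw(9)
  bad2_path <- tempfile()
  writeBin(bad2, bad2_path)
  expect_error(load_index(bad2_path), class = "fibkmer_format_error")
  # flipped payload byte -> checksum failure
  bad3 <- bytes; bad3[40] <- xor(bad3[40], as.raw(0xFF))
  bad3_path <- tempfile()
  writeBin(bad3, bad3_path)
  expect_error(load_index(bad3_path), class = "fibkmer_checksum_error")
})

test_that("fetch_region returns exact upper-cased subsequences with bounds checking", {
  contigs <- c(c1 = "ACGTACGT")
  expect_equal(fetch_region(contigs, "c1:2-5"), "CGTA")
  expect_equal(fetch_region(contigs, "c1:1-8"), "ACGTACGT")
  expect_equal(fetch_region(c(c1 = "acgtacgt"), "c1:2-5"), "CGTA")
  expect_error(fetch_region(contigs, "c1:6-12"), class = "fibkmer_out_of_bounds")
  expect_error(fetch_region(contigs, "cX:1-4"), class = "fibkmer_unknown_contig")
})

test_that("per-query probe cost does not grow with genome length", {
  probes <- vapply(c(1e3, 1e6), function(L) {
    g <- simulate_genome(35, lengths = as.integer(L))
    idx <- build_index(g, k = 21)
    set.seed(35)
    index_reset_counters(idx)
    for (rep in 1:200) {
      off <- sample(L - 21, 1)
      invisible(exact_query(idx, substr(g$contigs[[1]], off, off + 20)))
    }
    ctr <- index_counters(idx)
    ctr$probes / ctr$lookups
  }, numeric(1))
  expect_lt(probes[2], probes[1] * 2 + 1)
  expect_lt(max(probes), 6)
})
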
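test_that("genome simulation is deterministic and respects composition settings", {
  g1 <- simulate_genome(1, lengths = 100)
  g2 <- simulate_genome(1, lengths = 100)
  expect_identical(g1$contigs, g2$contigs)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(g1, f1); write_fasta(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # different seed, different genome
  expect_false(identical(simulate_genome(2, lengths = 100)$contigs, g1$contigs))
  # composition extremes
  gc1 <- simulate_genome(3, lengths = 500, gc = 1)
  expect_match(gc1$contigs[[1]], "^[GC]+$")
  at1 <- simulate_genome(3, lengths = 500, gc = 0)
  expect_match(at1$contigs[[1]], "^[AT]+$")
  # the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_genome(4, lengths = 50)); after <- runif(1)
  expect_identical(before, after)
})

test_that("explicit plantings land at the requested positions with the requested mismatches", {
  plant <- data.frame(source_contig = 1, source_start = 10, k = 25,
                      target_contig = 1, target_start = 60,
                      positions = "3,19", stringsAsFactors = FALSE)
  g <- simulate_genome(5, lengths = 200, plantings = plant)
  expect_equal(nrow(g$truth), 1)
  src <- substr(g$contigs[[1]], 10, 34)
  copy <- substr(g$contigs[[1]], 60, 84)
  expect_identical(src, g$truth$source_kmer)
  expect_identical(copy, g$truth$planted_kmer)
  h <- kmer_hamming(encode_kmer(src, 25), encode_kmer(copy, 25), 25)
  expect_equal(h$distance, 2L)
  expect_equal(h$positions, c(3L, 19L))
  # overlapping plantings are a configuration error
  bad <- rbind(plant, data.frame(source_contig = 1, source_start = 10, k = 25,
                                 target_contig = 1, target_start = 70,
                                 positions = "1"))
  expect_error(simulate_genome(5, lengths = 200, plantings = bad),
               class = "fibkmer_config_error")
  # out-of-bounds plantings too
  oob <- plant; oob$target_start <- 190
  expect_error(simulate_genome(5, lengths = 200, plantings = oob),
               class = "fibkmer_config_error")
})

test_that("random plantings record truthful distances and positions", {
  g <- simulate_genome(6, lengths = 5000, n_repeats = 8, repeat_k = 21, repeat_d = 1:2)
  expect_equal(nrow(g$truth), 8)
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    copy <- substr(g$contigs[[tr$target_contig]], tr$target_start,
                   tr$target_start + tr$k - 1)
    expect_identical(copy, tr$planted_kmer)
    h <- kmer_hamming(encode_kmer(tr$source_kmer, tr$k),
                      encode_kmer(copy, tr$k), tr$k)
    expect_equal(h$distance, tr$distance)
    expect_equal(paste(h$positions, collapse = ","), tr$positions)
  }
})

test_that("variant simulation is deterministic, reference-verified, and typed correctly", {
  g <- simulate_genome(7, lengths = 20000)
  sv1 <- simulate_variants(g, 7, n_snv = 5, n_ins = 3, n_del = 3,
                           indel_len = c(2, 2), k = 21)
  sv2 <- simulate_variants(g, 7, n_snv = 5, n_ins = 3, n_del = 3,
                           indel_len = c(2, 2), k = 21)
  expect_identical(sv1$variants, sv2$variants)
  v1 <- tempfile(); v2 <- tempfile()
  write_vcf(sv1, v1, genome = g); write_vcf(sv2, v2, genome = g)
  expect_identical(readLines(v1), readLines(v2))
  for (i in seq_len(nrow(sv1$variants))) {
    v <- sv1$variants[i, ]
    expect_identical(substr(g$contigs[[v$contig]], v$pos, v$pos + nchar(v$ref) - 1),
                     v$ref)
  }
  dels <- sv1$variants[sv1$variants$vtype == "DEL", ]
  expect_true(all(nchar(dels$ref) == 3 & nchar(dels$alt) == 1)) # anchor + 2 deleted
  ins <- sv1$variants[sv1$variants$vtype == "INS", ]
  expect_true(all(nchar(ins$alt) == 3 & nchar(ins$ref) == 1))
  af <- sv1$variants$af_AF
  expect_true(all(af >= 0 & af <= 1))
  expect_error(simulate_variants(simulate_genome(8, lengths = 100), 8,
                                 n_snv = 50, k = 21),
               class = "fibkmer_config_error")
})

test_that("the naive scan oracle enumerates matches by direct comparison", {
  hits <- naive_fuzzy_scan(c(c1 = "AAAAAAA"), "AAAT", d_max = 1)
  expect_equal(hits$offset, 0:3)
  expect_true(all(hits$distance == 1))
  expect_true(all(hits$positions == "4"))
  # a unique window matches itself exactly once
  g <- simulate_genome(9, lengths = 300)
  q <- substr(g$contigs[[1]], 100, 120)
  exact <- naive_fuzzy_scan(g, q, 0)
  expect_equal(nrow(exact), 1)
  expect_equal(exact$offset, 99)
  expect_equal(exact$distance, 0)
  # absent k-mer at d_max = 0
  expect_equal(nrow(naive_fuzzy_scan(c(c1 = "AAAA"), "CCCC", 0)), 0)
  # non-ACGT windows are skipped, as in the index
  expect_equal(naive_fuzzy_scan(c(c1 = "AANAAA"), "AAA", 1)$offset, c(3L))
})
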
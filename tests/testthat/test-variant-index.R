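test_that("alt windows embed the ALT allele in k-1 bases of context", {
  # SNV: substitution replaces the base, context k-1 per side
  aw <- alt_window("AAAAACCCCC", list(pos = 5, ref = "A", alt = "G"), k = 3)
  expect_equal(aw$alt_seq, "AAGCC")
  expect_equal(c(aw$altered_start, aw$altered_end), c(2L, 3L))
  expect_equal(aw$vtype, "SNV")
  # deletion: anchored REF/ALT, altered interval is the zero-length junction
  dw <- alt_window("ACGTACGT", list(pos = 3, ref = "GTA", alt = "G"), k = 3)
  expect_equal(dw$altered_start, dw$altered_end)
  expect_equal(dw$vtype, "DEL")
  # insertion: anchor base is context, inserted bases are the altered interval
  iw <- alt_window("AAATTT", list(pos = 3, ref = "A", alt = "AGG"), k = 3)
  expect_equal(iw$alt_seq, "AAGGTT")
  expect_equal(c(iw$altered_start, iw$altered_end), c(2L, 4L))
  expect_equal(iw$vtype, "INS")
  # REF mismatch is an error
  expect_error(alt_window("AAAAACCCCC", list(pos = 5, ref = "T", alt = "G"), 3),
               class = "fibkmer_reference_mismatch")
})

test_that("variant k-mer sets match hand enumeration for SNV, DEL and INS", {
  vk <- variant_kmers("AAAAACCCCC", list(pos = 5, ref = "A", alt = "G"), 3)
  expect_setequal(vk$kmer, c("AAG", "AGC", "GCC")) # k k-mers overlapping the SNV
  vk2 <- variant_kmers("ACGTACGT", list(pos = 3, ref = "GTA", alt = "G"), 3)
  expect_setequal(vk2$kmer, c("CGC", "GCG")) # k-1 k-mers spanning the junction
  vk3 <- variant_kmers("AAATTT", list(pos = 3, ref = "A", alt = "AGG"), 3)
  expect_setequal(vk3$kmer, c("AAG", "AGG", "GGT", "GTT")) # L + k - 1
})

test_that("variant k-mer counts obey L_alt + k - 1 with full context", {
  set.seed(51)
  g <- simulate_genome(51, lengths = 60000)
  sv <- simulate_variants(g, 51, n_snv = 40, n_ins = 30, n_del = 30,
                          indel_len = c(1, 5), k = 31)
  for (k in c(11L, 21L, 31L)) {
    for (i in seq_len(nrow(sv$variants))) {
      v <- sv$variants[i, ]
      vk <- variant_kmers(g, v, k)
      expected <- switch(v$vtype,
        SNV = k,
        INS = (nchar(v$alt) - 1) + k - 1,
        DEL = k - 1
      )
      expect_equal(nrow(vk), expected)
      # for substitutions, no generated k-mer equals the reference window at
      # the same alt-haplotype offset (indels in low-complexity context can
      # legitimately reproduce reference k-mers, e.g. a deletion in a
      # homopolymer, so the guarantee is substitution-only)
      if (v$vtype == "SNV") {
        g_start <- v$pos - (k - 1) # 1-based genome coordinate of alt_seq[1]
        contig_seq <- g$contigs[[v$contig]]
        for (j in seq_len(nrow(vk))) {
          ref_win <- substr(contig_seq, g_start + vk$offset[j],
                            g_start + vk$offset[j] + k - 1)
          expect_false(identical(vk$kmer[j], ref_win))
        }
      }
    }
  }
})

test_that("SNV alt k-mers are absent from the surrounding reference sequence", {
  g <- simulate_genome(52, lengths = 20000)
  sv <- simulate_variants(g, 52, n_snv = 10, k = 21)
  for (i in seq_len(nrow(sv$variants))) {
    v <- sv$variants[i, ]
    vk <- variant_kmers(g, v, 21)
    local_ref <- fetch_region(g, sprintf(
      "%s:%0.f-%0.f", v$contig,
      max(1, v$pos - 25), min(nchar(g$contigs[[v$contig]]), v$pos + 25)))
    for (j in seq_len(nrow(vk))) {
      expect_false(grepl(vk$kmer[j], local_ref, fixed = TRUE))
    }
  }
})

test_that("the bipartite index maps codes to all their variants and back", {
  ref <- c(c1 = "ACGTACGTAAGGCCTTACGTACGTACGGGTTTACAC")
  vars <- data.frame(
    contig = "c1", pos = c(10, 28),
    ref = c("A", "G"), alt = c("C", "A"),
    af_AF = c(0.1, 0.2), stringsAsFactors = FALSE
  )
  vidx <- build_variant_index(vars, ref, k = 5, af_keys = "AF")
  expect_equal(nrow(vidx$variants), 2)
  # well-separated SNVs: each code maps to exactly one variant
  expect_true(all(vapply(vidx$entries, nrow, integer(1)) == 1))
  expect_equal(length(vidx$entries), 10) # 2 variants x k codes, all distinct
  # engineered shared k-mer: two identical SNVs in identical context
  ref2 <- c(c1 = paste0("AAAAA", "TTGCA", "AAAAA", "TTGCA", "AAAAA"))
  vars2 <- data.frame(contig = "c1", pos = c(8, 18), ref = "G", alt = "C",
                      stringsAsFactors = FALSE)
  vidx2 <- build_variant_index(vars2, ref2, k = 3, af_keys = "AF")
  shared <- vapply(vidx2$entries, nrow, integer(1))
  expect_true(any(shared == 2)) # the bipartite many-to-many case
  # empty catalogue
  vidx3 <- build_variant_index(vars2[0, ], ref2, k = 3, af_keys = "AF")
  expect_equal(length(vidx3$entries), 0)
  expect_equal(nrow(query_variant_kmers(vidx3, ref2[[1]])), 0)
})

test_that("querying an alt haplotype recovers the planted variant on every overlapping window", {
  g <- simulate_genome(53, lengths = 30000)
  sv <- simulate_variants(g, 53, n_snv = 6, n_ins = 3, n_del = 3, k = 15)
  vidx <- build_variant_index(sv, g, k = 15, assembly_index = build_index(g, k = 15))
  expect_length(vidx$in_reference, length(vidx$entries))
  # SNV-derived codes can never be the reference window they replace; check
  # none of them are flagged (indel codes may legitimately recur in repeats)
  snv_ids <- sv$variants$variant_id[sv$variants$vtype == "SNV"]
  snv_entries <- vapply(vidx$entries, function(e) all(e[, "variant_id"] %in% snv_ids),
                        logical(1))
  expect_false(any(vidx$in_reference[snv_entries]))
  for (i in seq_len(nrow(sv$variants))) {
    v <- sv$variants[i, ]
    aw <- alt_window(g, v, 15)
    hits <- query_variant_kmers(vidx, aw$alt_seq)
    expect_true(all(hits$variant_id == v$variant_id))
    l_alt <- aw$altered_end - aw$altered_start
    expect_equal(nrow(hits), max(l_alt + 15 - 1, 15 - 1))
    expect_equal(unique(hits$vtype), v$vtype)
    expect_equal(unique(hits$af_AF), v$af_AF)
  }
  # pure reference sequence yields no variant hits
  expect_equal(nrow(query_variant_kmers(vidx, substr(g$contigs[[1]], 1, 500))), 0)
  # queries shorter than k yield an empty result
  expect_equal(nrow(query_variant_kmers(vidx, "ACGT")), 0)
})

test_that("alt-haplotype reads recover exactly the planted variants (precision = recall = 1)", {
  k <- 15L
  g <- simulate_genome(54, lengths = 40000)
  sv <- simulate_variants(g, 54, n_snv = 10, n_ins = 5, n_del = 5, k = k)
  vidx <- build_variant_index(sv, g, k = k)
  set.seed(54)
  truth_ids <- integer(0)
  found_ids <- integer(0)
  for (i in seq_len(nrow(sv$variants))) {
    v <- sv$variants[i, ]
    aw <- alt_window(g, v, k)
    # reads: substrings of the alt haplotype overlapping the altered interval
    for (rep in 1:5) {
      rl <- sample(k:(nchar(aw$alt_seq)), 1)
      start <- sample(max(1, aw$altered_end - rl + 1):min(aw$altered_start + 1,
                                                          nchar(aw$alt_seq) - rl + 1), 1)
      read <- substr(aw$alt_seq, start, start + rl - 1)
      hits <- query_variant_kmers(vidx, read)
      truth_ids <- c(truth_ids, v$variant_id)
      found_ids <- c(found_ids, if (nrow(hits)) unique(hits$variant_id) else NA_integer_)
    }
  }
  expect_false(anyNA(found_ids)) # recall = 1
  expect_equal(found_ids, truth_ids) # precision = 1
})

test_that("index construction is order-independent and VCF ingestion round-trips", {
  g <- simulate_genome(55, lengths = 20000)
  sv <- simulate_variants(g, 55, n_snv = 8, n_ins = 4, n_del = 4, k = 13,
                          af_keys = c("AF", "AF_afr"))
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(sv, vcf, genome = g)
  recs <- read_vcf_records(vcf, af_keys = c("AF", "AF_afr"))
  expect_equal(nrow(recs), nrow(sv$variants))
  expect_equal(recs$ref, sv$variants$ref)
  expect_equal(recs$af_AF, sv$variants$af_AF, tolerance = 1e-9)
  v1 <- build_variant_index(vcf, g, k = 13, af_keys = c("AF", "AF_afr"))
  shuffled <- recs[sample(nrow(recs)), ]
  v2 <- build_variant_index(shuffled, g, k = 13, af_keys = c("AF", "AF_afr"))
  for (i in seq_len(nrow(recs))) {
    aw <- alt_window(g, recs[i, ], 13)
    h1 <- query_variant_kmers(v1, aw$alt_seq)
    h2 <- query_variant_kmers(v2, aw$alt_seq)
    o1 <- order(h1$window_index, h1$variant_id)
    o2 <- order(h2$window_index, h2$variant_id)
    expect_equal(h1[o1, c("window_index", "variant_id", "pos", "ref", "alt")],
                 h2[o2, c("window_index", "variant_id", "pos", "ref", "alt")],
                 ignore_attr = TRUE)
  }
})

test_that("multi-allelic records split and per-allele AFs are assigned", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "c1\t5\t.\tA\tC,G\t.\tPASS\tAF=0.25,0.5",
    "c1\t9\t.\tT\tA\t.\tPASS\tDP=10"
  ), vcf)
  recs <- read_vcf_records(vcf, af_keys = "AF")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$alt, c("C", "G", "A"))
  expect_equal(recs$af_AF, c(0.25, 0.5, NA)) # missing AF is NA, not fatal
})

test_that("reference-present alt k-mers can be flagged or dropped", {
  # plant a variant whose alt k-mer also exists elsewhere in the reference
  ref <- c(c1 = paste0("TTTTT", "ACGTACG", "TTTTTTTT", "ACCTACG", "TTTTT"))
  # SNV G>C at pos 9 turns ACGTACG (pos 6..12) into ACCTACG == pos 21..27
  vars <- data.frame(contig = "c1", pos = 8, ref = "G", alt = "C",
                     stringsAsFactors = FALSE)
  aidx <- build_index(ref, k = 7)
  flagged <- build_variant_index(vars, ref, k = 7, assembly_index = aidx)
  expect_true(any(flagged$in_reference))
  dropped <- build_variant_index(vars, ref, k = 7, assembly_index = aidx,
                                 drop_reference_kmers = TRUE)
  expect_lt(length(dropped$entries), length(flagged$entries))
  expect_false(any(dropped$in_reference))
})

test_that("a variant index survives a save/load round trip, and BED export is sane", {
  g <- simulate_genome(56, lengths = 15000)
  sv <- simulate_variants(g, 56, n_snv = 5, n_ins = 2, n_del = 2, k = 13,
                          af_keys = c("AF", "AF_nfe"))
  vidx <- build_variant_index(sv, g, k = 13, af_keys = c("AF", "AF_nfe"))
  path <- tempfile(fileext = ".kmky")
  save_variant_index(vidx, path)
  v2 <- load_variant_index(path)
  expect_equal(v2$k, vidx$k)
  expect_equal(v2$af_keys, vidx$af_keys)
  for (i in seq_len(nrow(sv$variants))) {
    aw <- alt_window(g, sv$variants[i, ], 13)
    h1 <- query_variant_kmers(vidx, aw$alt_seq)
    h2 <- query_variant_kmers(v2, aw$alt_seq)
    expect_equal(h1, h2, ignore_attr = TRUE)
  }
  bed <- tempfile(fileext = ".bed")
  variant_bed(vidx, bed)
  lines <- read.delim(bed, header = FALSE)
  expect_equal(nrow(lines), nrow(sv$variants))
  dels <- sv$variants$vtype == "DEL"
  expect_true(all((lines$V3 - lines$V2)[order(sv$variants$pos)][dels[order(sv$variants$pos)]] > 1))
})
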
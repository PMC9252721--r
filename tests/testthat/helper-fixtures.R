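# Shared fixtures and comparison helpers. All fixtures are generated in code;
# the naive scan oracle defines ground truth for search results.

# Flatten fuzzy_query output to one row per matched genome location, the same
# shape naive_fuzzy_scan reports, sorted canonically for comparison.
expand_fuzzy <- function(fz) {
  if (nrow(fz) == 0L) {
    return(data.frame(contig = character(0), offset = numeric(0),
                      distance = integer(0), positions = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(fz)), function(i) {
    loc <- fz$locations[[i]]
    data.frame(contig = loc$contig, offset = loc$offset,
               distance = fz$distance[i], positions = fz$mismatch_positions[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$contig, out$offset), , drop = FALSE]
}

sort_scan <- function(df) {
  out <- df[order(df$contig, df$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_same_matches <- function(fz, naive) {
  a <- sort_scan(expand_fuzzy(fz))
  b <- sort_scan(naive)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$contig, b$contig)
  expect_equal(as.numeric(a$offset), as.numeric(b$offset))
  expect_equal(as.integer(a$distance), as.integer(b$distance))
  expect_equal(a$positions, b$positions)
}

# Mutate a k-mer at n random positions (plain string ops, shared test utility)
mutate_kmer <- function(kmer, n) {
  ch <- strsplit(kmer, "")[[1]]
  for (p in sample(length(ch), n)) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

random_kmer <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                                 collapse = "")
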
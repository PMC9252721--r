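# Genome k-mer index: every ACGT window of every contig, mapped to its count
# and locations through the Fibonacci hash table. A table value is tagged in
# its low bit: 0 = a single location inlined in the remaining 63 bits
# (contig ordinal 16 bits, 0-based offset 46 bits, strand 1 bit); 1 = an
# offset into the posting arena, whose entry holds the count followed by that
# many packed locations.

# Accept a FASTA path (.fa/.fa.gz, multi-contig, wrapped lines), a named
# character vector of contig sequences, or a simulated genome object.
.as_contigs <- function(x) {
  if (inherits(x, "sim_genome")) return(x$contigs)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x)) {
    dss <- Biostrings::readDNAStringSet(x)
    return(setNames(as.character(dss), sub("\\s.*$", "", names(dss))))
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  fk_stop("parse_error",
          "expected a FASTA path, a named character vector of contigs, or a sim_genome")
}

.contig_checksum <- function(contigs) {
  per_seq <- vapply(contigs, function(s) cpp_fnv1a(charToRaw(s)), character(1))
  blob <- paste(names(contigs), nchar(contigs), per_seq, sep = "\t", collapse = "\n")
  cpp_fnv1a(charToRaw(blob))
}

.new_genome_index <- function(ptr, checksum) {
  info <- cpp_index_info(ptr)
  structure(list(
    ptr = ptr,
    k = info$k,
    strand_mode = info$strand_mode,
    contigs = data.frame(name = info$contig_names, length = info$contig_lengths,
                         stringsAsFactors = FALSE),
    contig_checksum = checksum
  ), class = "genome_index")
}

#' Build a k-mer index over a genome assembly
#'
#' Indexes every k-mer window of every contig with its occurrence count and
#' all of its locations. Windows containing non-ACGT characters are skipped;
#' soft-masked lower-case bases are indexed as upper-case. Locations record
#' k-mers as written in the FASTA (forward strand); with
#' `strand_mode = "both"`, reverse-complement occurrences are matched at
#' query time instead of doubling the index.
#'
#' @param fasta FASTA path (optionally gzipped), named character vector of
#'   contig sequences, or a [simulate_genome()] result.
#' @param k k-mer length, 1..31.
#' @param strand_mode `"forward"` (default) or `"both"`.
#' @param b initial table size exponent (capacity 2^b slots; grows as
#'   needed).
#' @param max_load maximum hash-table load factor.
#' @return an object of class `genome_index`.
#' @examples
#' idx <- build_index(c(c1 = "ACGTACGT"), k = 4)
#' exact_query(idx, "ACGT")$count # 2
#' @export
build_index <- function(fasta, k, strand_mode = c("forward", "both"),
                        b = 16L, max_load = 0.7) {
  strand_mode <- match.arg(strand_mode)
  if (is.character(fasta) && length(fasta) == 0L)
    fk_stop("empty_input", "no sequence to index")
  contigs <- .as_contigs(fasta)
  if (length(contigs) == 0L || all(nchar(contigs) == 0L))
    fk_stop("empty_input", "no sequence to index")
  ptr <- wrap_cpp(cpp_index_build(contigs, as.integer(k),
                                  as.integer(strand_mode == "both"),
                                  as.integer(b), max_load))
  .new_genome_index(ptr, .contig_checksum(contigs))
}

.locations_df <- function(index, loc) {
  data.frame(
    contig = index$contigs$name[loc$contig_ord],
    offset = as.numeric(loc$offset),
    strand = loc$strand,
    stringsAsFactors = FALSE
  )
}

#' Exact k-mer query
#'
#' @param index a [build_index()] result.
#' @param query a k-base sequence or a packed code.
#' @return list with `count` (number of matching locations; 0 when absent)
#'   and `locations`, a data.frame of `contig`, `offset` (0-based) and
#'   `strand`. Under `strand_mode = "both"` the reverse-complement
#'   occurrences are included with strand `"-"`.
#' @export
exact_query <- function(index, query) {
  stopifnot(inherits(index, "genome_index"))
  res <- wrap_cpp(cpp_index_exact_query(index$ptr, .as_code(query, index$k)))
  list(count = as.integer(res$count), locations = .locations_df(index, res$locations))
}

#' Fuzzy k-mer query over a Hamming neighborhood
#'
#' Enumerates every code within `[d_min, d_max]` substitutions of the query
#' (at most two mismatches in the command-line interface) and performs one
#' exact table lookup per neighbor — `sum(3^d * choose(k, d))` lookups in
#' total, independent of genome size.
#'
#' @inheritParams exact_query
#' @param d_min,d_max mismatch bounds.
#' @return data.frame with one row per neighbor present in the index, sorted
#'   by `(distance, match_code)`: `match_kmer`, `match_code`, `distance`,
#'   `mismatch_positions` (comma-joined, 1-based from the 5' end), `count`,
#'   and a `locations` list-column of per-match location data.frames.
#' @export
fuzzy_query <- function(index, query, d_min = 0L, d_max = 2L) {
  stopifnot(inherits(index, "genome_index"))
  res <- wrap_cpp(cpp_index_fuzzy_query(index$ptr, .as_code(query, index$k),
                                        as.integer(d_min), as.integer(d_max)))
  n <- length(res$match_code)
  locs <- .locations_df(index, res$locations)
  split_locs <- if (n) {
    unname(split(locs, factor(res$locations$match, levels = seq_len(n))))
  } else {
    list()
  }
  out <- data.frame(
    match_kmer = if (n) decode_kmer(res$match_code, index$k) else character(0),
    match_code = res$match_code,
    distance = res$distance,
    mismatch_positions = res$positions,
    count = as.integer(res$count),
    stringsAsFactors = FALSE
  )
  out$locations <- split_locs
  out
}

#' Index statistics
#'
#' @param index a `genome_index`.
#' @return list with `k`, `strand_mode`, `n_distinct` (distinct keys),
#'   `n_windows` (total indexed windows, i.e. the sum of counts), contig
#'   table, hash-table geometry and probe counters.
#' @export
index_stats <- function(index) {
  stopifnot(inherits(index, "genome_index"))
  c(cpp_index_info(index$ptr), cpp_index_counters(index$ptr))
}

#' @rdname ht_counters
#' @param index a `genome_index`.
#' @export
index_counters <- function(index) {
  stopifnot(inherits(index, "genome_index"))
  cpp_index_counters(index$ptr)
}

#' @rdname ht_counters
#' @export
index_reset_counters <- function(index) {
  stopifnot(inherits(index, "genome_index"))
  cpp_index_reset_counters(index$ptr)
  invisible(index)
}

#' @export
print.genome_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("<genome_index> k=%d strand=%s | %s distinct k-mers, %s windows, %d contigs\n",
              info$k, info$strand_mode,
              format(info$n_distinct, big.mark = ","),
              format(info$n_windows, big.mark = ","),
              nrow(x$contigs)))
  invisible(x)
}

#' Fetch a subsequence by coordinates
#'
#' Coordinate queries retrieve the sequence at the specified interval, which
#' can then be decomposed into query k-mers.
#'
#' @param fasta FASTA path, named contig vector or `sim_genome`.
#' @param region a region string `"contig:start-end"` (1-based inclusive) or
#'   a [parse_region()] result.
#' @return the upper-cased subsequence.
#' @export
fetch_region <- function(fasta, region) {
  contigs <- .as_contigs(fasta)
  r <- if (is.character(region)) parse_region(region) else region
  if (!r$contig %in% names(contigs))
    fk_stop("unknown_contig", "contig '%s' not present", r$contig)
  len <- nchar(contigs[[r$contig]])
  if (r$end0 > len)
    fk_stop("out_of_bounds", "interval [%d,%d) exceeds contig '%s' length %d",
            r$start0, r$end0, r$contig, len)
  toupper(substr(contigs[[r$contig]], r$start0 + 1L, r$end0))
}

# ---- serialization: "KMKY" container -------------------------------------
# magic "KMKY" | version u32 | kind u8 (1 assembly, 2 variant) | k u8 |
# strand u8 | reserved u8 | contig table | contig checksum u64 |
# kind-specific sections | whole-file FNV-1a checksum u64. Little-endian.

.raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
.raw_u64 <- function(x) cpp_u64_to_raw(as_u64(x))

.read_u32 <- function(bytes, at) {
  if (at + 3L > length(bytes)) fk_stop("format_error", "truncated index file")
  readBin(bytes[at:(at + 3L)], "integer", size = 4L, endian = "little")
}

.read_u64 <- function(bytes, at) {
  if (at + 7L > length(bytes)) fk_stop("format_error", "truncated index file")
  cpp_raw_to_u64(bytes[at:(at + 7L)])
}

.serialize_contig_table <- function(contigs_df) {
  parts <- list(.raw_u32(nrow(contigs_df)))
  for (i in seq_len(nrow(contigs_df))) {
    nm <- charToRaw(contigs_df$name[i])
    parts <- c(parts, list(.raw_u32(length(nm)), nm, .raw_u64(contigs_df$length[i])))
  }
  do.call(c, parts)
}

.parse_contig_table <- function(bytes, at) {
  n <- .read_u32(bytes, at); at <- at + 4L
  nms <- character(n); lens <- numeric(n)
  for (i in seq_len(n)) {
    nl <- .read_u32(bytes, at); at <- at + 4L
    if (at + nl - 1L > length(bytes)) fk_stop("format_error", "truncated index file")
    nms[i] <- rawToChar(bytes[at:(at + nl - 1L)]); at <- at + nl
    lens[i] <- as.numeric(.read_u64(bytes, at)); at <- at + 8L
  }
  list(df = data.frame(name = nms, length = lens, stringsAsFactors = FALSE), at = at)
}

.write_kmky <- function(path, kind, k, strand_both, contigs_df, checksum, sections) {
  header <- c(charToRaw("KMKY"), .raw_u32(1L),
              as.raw(c(kind, k, strand_both, 0L)))
  body <- c(header, .serialize_contig_table(contigs_df), .raw_u64(checksum))
  for (s in sections) body <- c(body, .raw_u64(length(s)), s)
  body <- c(body, .raw_u64(cpp_fnv1a(body)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(body, con)
  invisible(path)
}

.read_kmky <- function(path, expect_kind) {
  if (!file.exists(path))
    fk_stop("format_error", "index file '%s' does not exist", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 24L) fk_stop("format_error", "truncated index file")
  if (rawToChar(bytes[1:4]) != "KMKY")
    fk_stop("format_error", "bad magic: not a KMKY index file")
  version <- .read_u32(bytes, 5L)
  if (version != 1L) fk_stop("format_error", "unsupported format version %d", version)
  stored_sum <- .read_u64(bytes, length(bytes) - 7L)
  if (cpp_fnv1a(bytes[1:(length(bytes) - 8L)]) != stored_sum)
    fk_stop("checksum_error", "index file checksum mismatch")
  kind <- as.integer(bytes[9L]); k <- as.integer(bytes[10L])
  strand_both <- as.integer(bytes[11L])
  if (kind != expect_kind)
    fk_stop("format_error", "wrong index kind (found %d, expected %d)", kind, expect_kind)
  ct <- .parse_contig_table(bytes, 13L)
  at <- ct$at
  checksum <- .read_u64(bytes, at); at <- at + 8L
  sections <- list()
  while (at < length(bytes) - 7L) {
    slen <- as.numeric(.read_u64(bytes, at)); at <- at + 8L
    if (at + slen - 1L > length(bytes) - 8L)
      fk_stop("format_error", "truncated index section")
    sections[[length(sections) + 1L]] <-
      if (slen > 0) bytes[at:(at + slen - 1L)] else raw(0)
    at <- at + slen
  }
  list(k = k, strand_both = strand_both, contigs = ct$df,
       contig_checksum = checksum, sections = sections)
}

#' Save / load a genome index
#'
#' The on-disk format is a little-endian "KMKY" container: header, contig
#' table with a checksum (so coordinate queries can verify a supplied FASTA
#' matches the index), the packed slot-metadata bitstream and value array of
#' the hash table, the posting arena, and a whole-file checksum. A loaded
#' index answers every query identically to the saved one.
#'
#' @param index a `genome_index`.
#' @param path file path.
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   `genome_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "genome_index"))
  .write_kmky(path, 1L, index$k, as.integer(index$strand_mode == "both"),
              index$contigs, index$contig_checksum,
              list(cpp_index_table_blob(index$ptr), cpp_arena_to_raw(index$ptr)))
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  f <- .read_kmky(path, 1L)
  if (length(f$sections) != 2L) fk_stop("format_error", "missing index sections")
  ptr <- wrap_cpp(cpp_index_from_blobs(f$sections[[1]], f$sections[[2]],
                                       f$k, f$strand_both,
                                       f$contigs$name, f$contigs$length))
  idx <- .new_genome_index(ptr, f$contig_checksum)
  idx
}

#' Verify that a FASTA matches the one an index was built from
#'
#' Compares the checksum of the supplied contig table (names, lengths and
#' per-contig sequence digests) against the one stored in the index.
#'
#' @param index a `genome_index` (or variant index).
#' @param fasta FASTA path or named contig vector.
#' @return `TRUE` invisibly, or an error of class `fibkmer_checksum_error`.
#' @export
verify_fasta <- function(index, fasta) {
  contigs <- .as_contigs(fasta)
  if (.contig_checksum(contigs) != index$contig_checksum)
    fk_stop("checksum_error",
            "supplied FASTA does not match the assembly this index was built from")
  invisible(TRUE)
}
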
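# K-mer representation of variants. A variant's k-mers are the k-windows of
# its alternate haplotype (the ALT allele embedded in up to k-1 reference
# bases of context per side) that overlap the altered bases, or that span
# the junction for deletions. A catalogue of variants indexed this way is a
# bipartite graph: k-mer keys on one side, variant records with their
# coordinate/allele/type/allele-frequency metadata on the other; a k-mer may
# map to several variants and a variant always maps to several k-mers.

.classify_variant <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr < 1L || la < 1L) fk_stop("parse_error", "empty REF or ALT allele")
  if (lr == 1L && la == 1L) return("SNV")
  if (lr == la) return("MNV")
  if (lr == 1L && la > 1L) return("INS")
  if (la == 1L && lr > 1L) return("DEL")
  "COMPLEX"
}

.variant_fields <- function(variant) {
  v <- as.list(variant)
  need <- c("pos", "ref", "alt")
  if (!all(need %in% names(v)))
    fk_stop("parse_error", "variant needs fields pos, ref, alt (and contig for multi-contig references)")
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  v$pos <- as.numeric(v$pos)
  v
}

#' Alternate-haplotype window of a variant
#'
#' Embeds the ALT allele in up to `k - 1` reference bases of flanking context
#' on each side of the altered interval, clipped at contig edges. For
#' left-anchored indels (VCF convention: REF and ALT share their first base)
#' the anchor base counts as context, not as altered sequence; a deletion's
#' altered interval is the zero-length junction between its flanks.
#'
#' @param reference named character vector of contig sequences (or a single
#'   unnamed sequence), a FASTA path, or a [simulate_genome()] result.
#' @param variant list or one-row data.frame with `contig`, `pos` (1-based),
#'   `ref`, `alt`. `contig` may be omitted when `reference` is a single
#'   sequence.
#' @param k k-mer length.
#' @return list with `alt_seq`, `altered_start`/`altered_end` (0-based
#'   half-open interval of the substituted/inserted bases within `alt_seq`;
#'   empty for deletions) and `vtype`.
#' @export
alt_window <- function(reference, variant, k) {
  v <- .variant_fields(variant)
  refseq <- if (is.character(reference) && length(reference) == 1L &&
                is.null(names(reference)) && !file.exists(reference)) {
    reference
  } else {
    contigs <- .as_contigs(reference)
    if (is.null(v$contig)) v$contig <- names(contigs)[1]
    if (!v$contig %in% names(contigs))
      fk_stop("unknown_contig", "contig '%s' not present in reference", v$contig)
    contigs[[v$contig]]
  }
  refseq <- toupper(refseq)
  lr <- nchar(v$ref)
  if (v$pos < 1 || v$pos + lr - 1 > nchar(refseq))
    fk_stop("out_of_bounds", "variant at %s:%0.f exceeds contig bounds", v$contig, v$pos)
  if (substr(refseq, v$pos, v$pos + lr - 1) != v$ref)
    fk_stop("reference_mismatch",
            "REF allele '%s' does not match reference at %s:%0.f (found '%s')",
            v$ref, if (is.null(v$contig)) "?" else v$contig, v$pos,
            substr(refseq, v$pos, v$pos + lr - 1))
  vtype <- .classify_variant(v$ref, v$alt)
  anchored <- nchar(v$ref) != nchar(v$alt) &&
    substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L)
  alt_core <- if (anchored) substr(v$alt, 2L, nchar(v$alt)) else v$alt
  left_end <- if (anchored) v$pos else v$pos - 1   # last unaltered ref base on the left
  right_start <- v$pos + lr                        # first unaltered ref base on the right
  left_ctx <- substr(refseq, max(1, left_end - (k - 1) + 1), left_end)
  right_ctx <- substr(refseq, right_start, min(nchar(refseq), right_start + k - 2))
  list(
    alt_seq = paste0(left_ctx, alt_core, right_ctx),
    altered_start = nchar(left_ctx),
    altered_end = nchar(left_ctx) + nchar(alt_core),
    vtype = vtype
  )
}

#' K-mers generated by a variant
#'
#' The k-windows of the variant's alternate haplotype that overlap the
#' substituted/inserted bases — or, for a deletion, that contain both bases
#' adjacent to the junction. With full flanking context the number of k-mers
#' is `L_alt + k - 1` where `L_alt` is the altered length: `k` for an SNV,
#' `k - 1` for a deletion, `L + k - 1` for an insertion of `L` bases. Fewer
#' are produced near contig edges; windows containing non-ACGT bases are
#' skipped.
#'
#' @inheritParams alt_window
#' @return data.frame with columns `code`, `kmer` and `offset` (0-based
#'   window offset within the alternate haplotype).
#' @export
variant_kmers <- function(reference, variant, k) {
  aw <- alt_window(reference, variant, k)
  win <- kmer_windows(aw$alt_seq, k)
  a <- aw$altered_start; b <- aw$altered_end
  keep <- if (a == b) {
    # deletion junction: window must contain both adjacent bases
    win$offset <= a - 1L & win$offset + k - 1L >= a
  } else {
    win$offset < b & win$offset + k > a
  }
  out <- win[keep, c("code", "kmer", "offset")]
  rownames(out) <- NULL
  out
}

#' Read and normalise VCF records
#'
#' Reads CHROM/POS/REF/ALT and the requested INFO allele-frequency fields,
#' splitting multi-allelic records into one record per ALT (with per-allele
#' AF values where the field is comma-separated). Missing AF fields are
#' recorded as `NA`, not treated as fatal.
#'
#' @param vcf path to a VCF (optionally gzipped).
#' @param af_keys character vector of INFO keys to carry as allele
#'   frequencies.
#' @return data.frame with `contig`, `pos`, `ref`, `alt`, `vtype`,
#'   `variant_id` and one `af_<key>` column per requested key.
#' @export
read_vcf_records <- function(vcf, af_keys = "AF") {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  info <- if (n > 0) v@fix[, "INFO"] else character(0)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    afs <- lapply(af_keys, function(key) {
      val <- sub(sprintf(".*(?:^|;)%s=([^;]*).*", key), "\\1", info[i])
      if (identical(val, info[i]) ||
          !grepl(sprintf("(^|;)%s=", key), info[i])) return(rep(NA_real_, length(alts)))
      parts <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1]]))
      if (length(parts) == length(alts)) parts else rep(parts[1], length(alts))
    })
    rows[[i]] <- data.frame(
      contig = unname(fix[i, "CHROM"]), pos = as.numeric(fix[i, "POS"]),
      ref = toupper(unname(fix[i, "REF"])), alt = toupper(alts),
      stringsAsFactors = FALSE, row.names = NULL
    )
    for (j in seq_along(af_keys)) rows[[i]][[paste0("af_", af_keys[j])]] <- afs[[j]]
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), pos = numeric(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
    for (key in af_keys) out[[paste0("af_", key)]] <- numeric(0)
  }
  out$vtype <- if (nrow(out)) mapply(.classify_variant, out$ref, out$alt) else character(0)
  out$variant_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build a bipartite k-mer-to-variant index
#'
#' Generates every variant's k-mers via [variant_kmers()] and indexes them in
#' a Fibonacci hash table mapping each code to the variants that produce it
#' (shared k-mers map to several variants). Records whose REF allele does not
#' match the reference are logged and skipped. The result is independent of
#' the order of VCF records.
#'
#' When `assembly_index` is supplied, variant k-mers that also occur in the
#' assembly are flagged `in_reference`; with `drop_reference_kmers = TRUE`
#' they are excluded from the queryable table instead.
#'
#' @param vcf VCF path or a [read_vcf_records()] / [simulate_variants()]
#'   data.frame.
#' @param reference FASTA path, named contig vector or [simulate_genome()].
#' @param k k-mer length.
#' @param af_keys INFO keys carried as allele frequencies (used when `vcf` is
#'   a path).
#' @param drop_reference_kmers drop codes present in `assembly_index`.
#' @param assembly_index optional [build_index()] of the same reference.
#' @param b,max_load hash-table geometry.
#' @return an object of class `variant_index`.
#' @export
build_variant_index <- function(vcf, reference, k, af_keys = "AF",
                                drop_reference_kmers = FALSE,
                                assembly_index = NULL,
                                b = 16L, max_load = 0.7) {
  contigs <- .as_contigs(reference)
  variants <- if (is.character(vcf) && length(vcf) == 1L) {
    read_vcf_records(vcf, af_keys)
  } else if (inherits(vcf, "sim_variants")) {
    vcf$variants
  } else {
    vcf
  }
  if (is.null(variants$variant_id)) variants$variant_id <- seq_len(nrow(variants))
  if (is.null(variants$vtype) && nrow(variants) > 0)
    variants$vtype <- mapply(.classify_variant, variants$ref, variants$alt)

  table <- fib_table(b = b, max_load = max_load)
  env <- new.env(parent = emptyenv()) # code -> entry ordinal, build-time scratch
  entries <- list()
  entry_codes <- character(0)
  skipped <- 0L
  keep <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    vk <- tryCatch(
      variant_kmers(contigs, variants[i, ], k),
      fibkmer_reference_mismatch = function(e) {
        message(sprintf("skipping variant %s:%s %s>%s: %s",
                        variants$contig[i], format(variants$pos[i], scientific = FALSE),
                        variants$ref[i], variants$alt[i], conditionMessage(e)))
        NULL
      }
    )
    if (is.null(vk)) { skipped <- skipped + 1L; keep[i] <- FALSE; next }
    for (j in seq_len(nrow(vk))) {
      code <- vk$code[j]
      ord <- env[[code]]
      if (is.null(ord)) {
        ord <- length(entries) + 1L
        env[[code]] <- ord
        entries[[ord]] <- cbind(variant_id = numeric(0), offset = numeric(0))
        entry_codes[ord] <- code
        ht_insert(table, code, ord)
      }
      entries[[ord]] <- rbind(entries[[ord]],
                              c(variant_id = variants$variant_id[i],
                                offset = vk$offset[j]))
    }
  }
  in_reference <- rep(FALSE, length(entries))
  if (!is.null(assembly_index)) {
    for (ord in seq_along(entries))
      in_reference[ord] <- exact_query(assembly_index, entry_codes[ord])$count > 0
    if (drop_reference_kmers && any(in_reference)) {
      kept <- which(!in_reference)
      remap <- setNames(seq_along(kept), kept)
      table <- fib_table(b = b, max_load = max_load)
      if (length(kept)) ht_insert(table, entry_codes[kept], seq_along(kept))
      entries <- entries[kept]
      entry_codes <- entry_codes[kept]
      in_reference <- rep(FALSE, length(entries))
    }
  }
  structure(list(
    table = table,
    entries = entries,
    entry_codes = entry_codes,
    in_reference = in_reference,
    variants = variants[keep, , drop = FALSE],
    k = k,
    af_keys = af_keys,
    n_skipped = skipped,
    contigs = data.frame(name = names(contigs), length = nchar(contigs),
                         stringsAsFactors = FALSE),
    contig_checksum = .contig_checksum(contigs)
  ), class = "variant_index")
}

#' @export
print.variant_index <- function(x, ...) {
  cat(sprintf("<variant_index> k=%d | %d variants, %d distinct k-mers (%d flagged in reference)\n",
              x$k, nrow(x$variants), length(x$entries), sum(x$in_reference)))
  invisible(x)
}

#' Query a sequence against a variant index
#'
#' Decomposes `seq` into k-mer windows and reports, for every window whose
#' code belongs to a variant's k-mer set, the matched variant with its
#' coordinate, alleles, type and allele-frequency metadata.
#'
#' @param vindex a [build_variant_index()] result.
#' @param seq query DNA string.
#' @return data.frame with one row per (window, variant) hit: `window_index`
#'   (1-based), `kmer`, `variant_id`, `contig`, `pos`, `ref`, `alt`,
#'   `vtype`, `alt_offset` (window offset within the variant's alternate
#'   haplotype), `in_reference`, and the `af_*` columns. Empty when
#'   `nchar(seq) < k` or nothing matches.
#' @export
query_variant_kmers <- function(vindex, seq) {
  stopifnot(inherits(vindex, "variant_index"))
  af_cols <- paste0("af_", vindex$af_keys)
  empty <- cbind(
    data.frame(window_index = integer(0), kmer = character(0),
               variant_id = numeric(0), contig = character(0), pos = numeric(0),
               ref = character(0), alt = character(0), vtype = character(0),
               alt_offset = numeric(0), in_reference = logical(0),
               stringsAsFactors = FALSE),
    setNames(as.data.frame(matrix(numeric(0), 0, length(af_cols))), af_cols)
  )
  win <- kmer_windows(seq, vindex$k)
  if (nrow(win) == 0L) return(empty)
  ords <- ht_lookup(vindex$table, win$code)
  hit <- which(!is.na(ords))
  if (length(hit) == 0L) return(empty)
  meta <- vindex$variants
  rows <- lapply(hit, function(i) {
    e <- vindex$entries[[as.integer(ords[i])]]
    m <- meta[match(e[, "variant_id"], meta$variant_id), , drop = FALSE]
    data.frame(
      window_index = win$offset[i] + 1L, kmer = win$kmer[i],
      variant_id = e[, "variant_id"], contig = m$contig, pos = m$pos,
      ref = m$ref, alt = m$alt, vtype = m$vtype, alt_offset = e[, "offset"],
      in_reference = vindex$in_reference[[as.integer(ords[i])]],
      m[, af_cols, drop = FALSE],
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- serialization --------------------------------------------------------

.variants_tsv_raw <- function(df) {
  con <- rawConnection(raw(0), "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  rawConnectionValue(con)
}

#' Save / load a variant index
#'
#' Shares the "KMKY" container with [save_index()], with a record-store
#' section holding the bipartite entries and the variant metadata table.
#'
#' @param vindex a `variant_index`.
#' @param path file path.
#' @return `save_variant_index` returns `path` invisibly; `load_variant_index`
#'   the restored `variant_index`.
#' @export
save_variant_index <- function(vindex, path) {
  stopifnot(inherits(vindex, "variant_index"))
  ent <- vindex$entries
  # entries section: n, then per entry (in_ref, n_pairs, pairs...); codes go
  # in their own section as exact u64 values
  flat_raw <- cpp_u64_to_raw(as_u64(c(length(ent), unlist(lapply(seq_along(ent), function(i) {
    e <- ent[[i]]
    c(as.numeric(vindex$in_reference[i]), nrow(e), as.numeric(t(e)))
  })))))
  codes_raw <- cpp_u64_to_raw(as_u64(c(length(vindex$entry_codes), vindex$entry_codes)))
  meta_raw <- .variants_tsv_raw(vindex$variants)
  keys_raw <- charToRaw(paste(vindex$af_keys, collapse = "\t"))
  .write_kmky(path, 2L, vindex$k, 0L, vindex$contigs, vindex$contig_checksum,
              list(cpp_table_to_blob(vindex$table$ptr), flat_raw, codes_raw,
                   meta_raw, keys_raw))
}

#' @rdname save_variant_index
#' @export
load_variant_index <- function(path) {
  f <- .read_kmky(path, 2L)
  if (length(f$sections) != 5L) fk_stop("format_error", "missing variant index sections")
  tbl <- structure(list(ptr = wrap_cpp(cpp_table_from_blob(f$sections[[1]]))),
                   class = "fib_table")
  flat <- as.numeric(cpp_raw_to_u64(f$sections[[2]]))
  codes_v <- cpp_raw_to_u64(f$sections[[3]])
  n_entries <- flat[1]
  if (as.numeric(codes_v[1]) != n_entries)
    fk_stop("format_error", "entry/code section mismatch")
  entry_codes <- codes_v[-1]
  entries <- vector("list", n_entries)
  in_reference <- logical(n_entries)
  at <- 2L
  for (i in seq_len(n_entries)) {
    in_reference[i] <- flat[at] == 1; at <- at + 1L
    np <- flat[at]; at <- at + 1L
    vals <- if (np > 0) flat[at:(at + 2 * np - 1)] else numeric(0)
    m <- matrix(vals, ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("variant_id", "offset")))
    entries[[i]] <- m
    at <- at + 2L * np
  }
  variants <- read.delim(text = rawToChar(f$sections[[4]]), sep = "\t",
                         stringsAsFactors = FALSE)
  af_keys <- strsplit(rawToChar(f$sections[[5]]), "\t", fixed = TRUE)[[1]]
  structure(list(
    table = tbl, entries = entries, entry_codes = entry_codes,
    in_reference = in_reference, variants = variants, k = f$k,
    af_keys = af_keys, n_skipped = 0L, contigs = f$contigs,
    contig_checksum = f$contig_checksum
  ), class = "variant_index")
}

#' Export a variant index as BED
#'
#' One line per variant, 0-based half-open over the REF allele span, with
#' REF/ALT/type and the allele-frequency columns — a coordinate-sorted,
#' tabix-friendly flat view of the catalogue.
#'
#' @param vindex a `variant_index` (or a variant data.frame).
#' @param path output path.
#' @return the path, invisibly.
#' @export
variant_bed <- function(vindex, path) {
  df <- if (inherits(vindex, "variant_index")) vindex$variants else vindex
  af_cols <- grep("^af_", names(df), value = TRUE)
  bed <- data.frame(
    chrom = df$contig,
    start = format(df$pos - 1, scientific = FALSE, trim = TRUE),
    end = format(df$pos - 1 + nchar(df$ref), scientific = FALSE, trim = TRUE),
    ref = df$ref, alt = df$alt, vtype = df$vtype,
    stringsAsFactors = FALSE
  )
  bed <- cbind(bed, df[, af_cols, drop = FALSE])
  bed <- bed[order(bed$chrom, as.numeric(bed$start)), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
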
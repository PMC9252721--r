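# Seeded synthetic data: genomes with planted approximate repeats at known
# Hamming distances, variant sets with reference-verified alleles, and the
# brute-force scan oracle that defines ground truth for every search
# operation. The oracle works by direct character comparison only — it
# shares no code with the codec or hash modules, so equivalence tests
# against it are meaningful.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.mutate_at <- function(kmer, positions) {
  ch <- strsplit(kmer, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate a genome with planted approximate repeats
#'
#' Generates random contigs at a given GC fraction, then plants copies of
#' source k-mers at chosen (or random) target positions, mutated at exactly
#' the requested 1-based positions, so every planting's Hamming distance and
#' mismatch positions are known. Plantings are placed non-overlapping so
#' truth counting is unambiguous. Deterministic: the same seed and
#' parameters reproduce the genome byte for byte; the caller's RNG state is
#' left untouched.
#'
#' @param seed integer seed.
#' @param lengths contig length(s) in bp.
#' @param names contig names (default `contig1`, ...).
#' @param gc GC fraction in `[0, 1]` (default 0.41, human-like).
#' @param plantings optional data.frame with columns `source_contig`,
#'   `source_start` (1-based), `k`, `target_contig`, `target_start`,
#'   `positions` (comma-joined 1-based mutation positions, `""` for an exact
#'   copy). Contigs may be names or ordinals.
#' @param n_repeats number of additional random plantings.
#' @param repeat_k k-mer length of random plantings.
#' @param repeat_d candidate Hamming distances for random plantings
#'   (sampled uniformly).
#' @return object of class `sim_genome`: list with `contigs` (named character
#'   vector), `truth` (one row per planting: source/target coordinates,
#'   `k`, `distance`, `positions`, `source_kmer`, `planted_kmer`), `seed`,
#'   `gc`.
#' @export
simulate_genome <- function(seed, lengths = 10000L, names = NULL, gc = 0.41,
                            plantings = NULL, n_repeats = 0L, repeat_k = 25L,
                            repeat_d = 1:2) {
  stopifnot(gc >= 0, gc <= 1, all(lengths >= 1))
  if (is.null(names)) names <- paste0("contig", seq_along(lengths))
  .with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    contigs <- setNames(vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1)), names)

    used <- lapply(seq_along(contigs), function(i) cbind(numeric(0), numeric(0)))
    overlaps <- function(ci, s, e) {
      u <- used[[ci]]
      any(u[, 1] <= e & u[, 2] >= s)
    }
    reserve <- function(ci, s, e) used[[ci]] <<- rbind(used[[ci]], c(s, e))

    truth <- list()
    add_planting <- function(sci, ss, k, tci, ts, positions) {
      if (ss < 1 || ss + k - 1 > nchar(contigs[[sci]]) ||
          ts < 1 || ts + k - 1 > nchar(contigs[[tci]]))
        fk_stop("config_error", "planting exceeds contig bounds")
      if (overlaps(tci, ts, ts + k - 1) ||
          (sci == tci && ss <= ts + k - 1 && ss + k - 1 >= ts))
        fk_stop("config_error", "planting target overlaps a source or another target")
      src <- substr(contigs[[sci]], ss, ss + k - 1)
      planted <- if (length(positions)) .mutate_at(src, positions) else src
      contigs[[tci]] <<- paste0(
        substr(contigs[[tci]], 1, ts - 1), planted,
        substr(contigs[[tci]], ts + k, nchar(contigs[[tci]]))
      )
      reserve(tci, ts, ts + k - 1)
      reserve(sci, ss, ss + k - 1)
      truth[[length(truth) + 1L]] <<- data.frame(
        source_contig = names(contigs)[sci], source_start = ss,
        target_contig = names(contigs)[tci], target_start = ts,
        k = k, distance = length(positions),
        positions = paste(positions, collapse = ","),
        source_kmer = src, planted_kmer = planted,
        stringsAsFactors = FALSE
      )
    }

    .ord <- function(x) {
      if (is.numeric(x)) as.integer(x) else match(x, names(contigs))
    }
    if (!is.null(plantings)) {
      for (i in seq_len(nrow(plantings))) {
        p <- plantings[i, ]
        pos <- if (nzchar(p$positions))
          as.integer(strsplit(p$positions, ",")[[1]]) else integer(0)
        add_planting(.ord(p$source_contig), p$source_start, p$k,
                     .ord(p$target_contig), p$target_start, pos)
      }
    }
    for (i in seq_len(n_repeats)) {
      placed <- FALSE
      for (try in 1:200) {
        sci <- sample(length(contigs), 1L)
        tci <- sample(length(contigs), 1L)
        if (nchar(contigs[[sci]]) < repeat_k || nchar(contigs[[tci]]) < repeat_k) next
        ss <- sample(nchar(contigs[[sci]]) - repeat_k + 1L, 1L)
        ts <- sample(nchar(contigs[[tci]]) - repeat_k + 1L, 1L)
        d <- if (length(repeat_d) == 1L) repeat_d else sample(repeat_d, 1L)
        pos <- sort(sample(repeat_k, d))
        ok <- tryCatch({
          add_planting(sci, ss, repeat_k, tci, ts, pos)
          TRUE
        }, fibkmer_config_error = function(e) FALSE)
        if (ok) { placed <- TRUE; break }
      }
      if (!placed)
        fk_stop("config_error", "could not place planting %d without overlap", i)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      source_contig = character(0), source_start = integer(0),
      target_contig = character(0), target_start = integer(0), k = integer(0),
      distance = integer(0), positions = character(0),
      source_kmer = character(0), planted_kmer = character(0),
      stringsAsFactors = FALSE
    )
    structure(list(contigs = contigs, truth = truth, seed = seed, gc = gc),
              class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> seed=%s | %d contig(s), %s bp, %d planting(s)\n",
              format(x$seed), length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated genome as FASTA
#'
#' The generating seed is recorded on each description line.
#'
#' @param genome a [simulate_genome()] result or named character vector.
#' @param path output path (`.gz` for compressed).
#' @return the path, invisibly.
#' @export
write_fasta <- function(genome, path) {
  contigs <- .as_contigs(genome)
  dss <- Biostrings::DNAStringSet(contigs)
  names(dss) <- if (inherits(genome, "sim_genome")) {
    paste0(names(contigs), " seed=", genome$seed)
  } else {
    names(contigs)
  }
  Biostrings::writeXStringSet(dss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate a variant set over a genome
#'
#' Places SNVs, insertions and deletions at ACGT loci with full `k - 1`
#' flanking context and no mutual overlap, REF alleles read from (and hence
#' verified against) the genome, and uniform allele-frequency values per
#' requested key. Deterministic under the seed.
#'
#' @param genome a [simulate_genome()] result or named contig vector.
#' @param seed integer seed.
#' @param n_snv,n_ins,n_del counts per variant type.
#' @param indel_len inclusive range of inserted/deleted lengths.
#' @param k downstream k-mer length (controls required flanking context).
#' @param af_keys allele-frequency INFO keys to generate.
#' @return object of class `sim_variants`: list with `variants` (a
#'   [read_vcf_records()]-shaped data.frame), `seed`, `af_keys`, `k`.
#' @export
simulate_variants <- function(genome, seed, n_snv = 5L, n_ins = 0L, n_del = 0L,
                              indel_len = c(1L, 5L), k = 31L, af_keys = "AF") {
  contigs <- .as_contigs(genome)
  .with_seed(seed, {
    max_len <- max(indel_len)
    pad <- k + max_len + 1L
    types <- c(rep("SNV", n_snv), rep("INS", n_ins), rep("DEL", n_del))
    if (length(types) == 0L)
      fk_stop("config_error", "no variants requested")
    taken <- lapply(contigs, function(x) numeric(0))
    rows <- vector("list", length(types))
    for (i in seq_along(types)) {
      placed <- FALSE
      for (try in 1:500) {
        ci <- sample(length(contigs), 1L)
        L <- nchar(contigs[[ci]])
        if (L < 2 * pad + 2) next
        pos <- sample(seq.int(pad, L - pad), 1L)
        if (any(abs(taken[[ci]] - pos) < pad)) next
        ref1 <- substr(contigs[[ci]], pos, pos)
        vt <- types[i]
        lens <- seq.int(indel_len[1], indel_len[2])
        if (vt == "SNV") {
          ref <- ref1
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref1), 1L)
        } else if (vt == "INS") {
          len <- lens[sample.int(length(lens), 1L)]
          ref <- ref1
          alt <- paste0(ref1, paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = ""))
        } else {
          len <- lens[sample.int(length(lens), 1L)]
          ref <- substr(contigs[[ci]], pos, pos + len)
          alt <- ref1
        }
        taken[[ci]] <- c(taken[[ci]], pos)
        rows[[i]] <- data.frame(contig = names(contigs)[ci], pos = pos,
                                ref = ref, alt = alt, vtype = vt,
                                stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        fk_stop("config_error", "genome too small to place %d variants", length(types))
    }
    variants <- do.call(rbind, rows)
    variants <- variants[order(variants$contig, variants$pos), , drop = FALSE]
    for (key in af_keys)
      variants[[paste0("af_", key)]] <- round(runif(nrow(variants)), 6)
    variants$variant_id <- seq_len(nrow(variants))
    rownames(variants) <- NULL
    structure(list(variants = variants, seed = seed, af_keys = af_keys, k = k),
              class = "sim_variants")
  })
}

#' @export
print.sim_variants <- function(x, ...) {
  cat(sprintf("<sim_variants> seed=%s | %s\n", format(x$seed),
              paste(sprintf("%s=%d", names(table(x$variants$vtype)),
                            as.integer(table(x$variants$vtype))), collapse = " ")))
  invisible(x)
}

#' Write a simulated variant set as VCF
#'
#' Records the seed in the header; one INFO field of Number=A floats per
#' allele-frequency key.
#'
#' @param variants a [simulate_variants()] result (or compatible data.frame
#'   plus `af_keys`).
#' @param path output path.
#' @param genome optional genome for `##contig` header lines.
#' @param af_keys allele-frequency keys (taken from the object when absent).
#' @return the path, invisibly.
#' @export
write_vcf <- function(variants, path, genome = NULL, af_keys = NULL) {
  if (inherits(variants, "sim_variants")) {
    if (is.null(af_keys)) af_keys <- variants$af_keys
    seed <- variants$seed
    df <- variants$variants
  } else {
    df <- variants
    seed <- NA
    if (is.null(af_keys)) af_keys <- sub("^af_", "", grep("^af_", names(df), value = TRUE))
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=fibkmer simulate_variants",
    if (!is.na(seed)) sprintf("##seed=%s", format(seed, scientific = FALSE))
  )
  if (!is.null(genome)) {
    contigs <- .as_contigs(genome)
    lines <- c(lines, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                              nchar(contigs)))
  }
  lines <- c(lines, sprintf(
    "##INFO=<ID=%s,Number=A,Type=Float,Description=\"Allele frequency\">", af_keys))
  lines <- c(lines, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(af_keys, function(key) {
      v <- df[[paste0("af_", key)]][i]
      sprintf("%s=%s", key, ifelse(is.na(v), ".", format(v, scientific = FALSE)))
    }, character(1)), collapse = ";")
  }, character(1))
  recs <- sprintf("%s\t%s\t.\t%s\t%s\t.\tPASS\t%s",
                  df$contig, format(df$pos, scientific = FALSE, trim = TRUE),
                  df$ref, df$alt, info)
  writeLines(c(lines, recs), path)
  invisible(path)
}

#' Brute-force fuzzy scan oracle
#'
#' Computes the Hamming distance of a query k-mer against every window of
#' every contig by direct character comparison — no hashing, no bit packing,
#' no shared code with the index. Windows containing non-ACGT characters are
#' skipped, matching the indexing rule.
#'
#' @param fasta FASTA path, named contig vector or [simulate_genome()].
#' @param query query k-mer (plain ACGT string).
#' @param d_max maximum Hamming distance reported.
#' @return data.frame with one row per matching window: `contig`, `offset`
#'   (0-based), `distance`, `positions` (comma-joined 1-based mismatch
#'   positions), sorted by contig order then offset.
#' @export
naive_fuzzy_scan <- function(fasta, query, d_max = 2L) {
  contigs <- .as_contigs(fasta)
  q <- strsplit(toupper(query), "")[[1]]
  k <- length(q)
  out <- list()
  for (ci in seq_along(contigs)) {
    g <- strsplit(toupper(contigs[[ci]]), "")[[1]]
    n_win <- length(g) - k + 1L
    if (n_win < 1L) next
    mism <- integer(n_win)
    valid <- rep(TRUE, n_win)
    for (j in seq_len(k)) {
      gs <- g[j:(j + n_win - 1L)]
      mism <- mism + (gs != q[j])
      valid <- valid & gs %in% c("A", "C", "G", "T")
    }
    hits <- which(valid & mism <= d_max)
    if (length(hits) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      contig = names(contigs)[ci],
      offset = hits - 1L,
      distance = mism[hits],
      positions = vapply(hits, function(h) {
        paste(which(g[h:(h + k - 1L)] != q), collapse = ",")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(0), offset = integer(0),
                      distance = integer(0), positions = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
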
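# Per-window fuzzy reporting: the summary view counts genome locations per
# mismatch distance for every query window; the detailed view lists each
# matching neighbor sequence with its locations and a dot-notation rendering.

.all_windows <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) {
    return(data.frame(window_index = integer(0), kmer = character(0),
                      code = character(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE))
  }
  valid <- kmer_windows(seq, k)
  idx <- seq_len(L - k + 1L)
  code <- rep(NA_character_, length(idx))
  code[valid$offset + 1L] <- valid$code
  data.frame(
    window_index = idx,
    kmer = substring(seq, idx, idx + k - 1L),
    code = code,
    ambiguous = is.na(code),
    stringsAsFactors = FALSE
  )
}

#' Summarize fuzzy matches for every window of a query sequence
#'
#' One row per k-mer window of `seq`, in sequence order, counting the genome
#' locations matched at each mismatch distance: exact, one mismatch, two
#' mismatches. Counts tally locations, not distinct neighbor sequences.
#' Windows containing non-ACGT characters are kept (so window indices stay
#' aligned with query coordinates) but flagged `ambiguous` with `NA` counts,
#' as are distances beyond `d_max`.
#'
#' @param index a [build_index()] result.
#' @param seq query sequence (any length `>= k`).
#' @param d_max maximum mismatches searched (0..2).
#' @return data.frame with columns `window_index` (1-based), `kmer`,
#'   `n_exact`, `n_mm1`, `n_mm2`, `ambiguous`.
#' @export
summarize_windows <- function(index, seq, d_max = 2L) {
  stopifnot(inherits(index, "genome_index"), d_max >= 0L, d_max <= 2L)
  win <- .all_windows(seq, index$k)
  n <- nrow(win)
  counts <- matrix(NA_integer_, nrow = n, ncol = 3L)
  for (i in seq_len(n)) {
    if (win$ambiguous[i]) next
    fm <- fuzzy_query(index, win$code[i], 0L, d_max)
    for (d in 0:d_max) counts[i, d + 1L] <- sum(fm$count[fm$distance == d])
  }
  data.frame(
    window_index = win$window_index,
    kmer = win$kmer,
    n_exact = counts[, 1L],
    n_mm1 = counts[, 2L],
    n_mm2 = counts[, 3L],
    ambiguous = win$ambiguous,
    stringsAsFactors = FALSE
  )
}

#' Detailed fuzzy matches for every window of a query sequence
#'
#' One row per (window, matching neighbor) pair, ordered by
#' `(window_index, distance, match_code)`. Each row carries the dot-notation
#' rendering of the match against the query window, the location count and
#' the rendered locations. Ambiguous windows produce no rows.
#'
#' @inheritParams summarize_windows
#' @param d_min,d_max mismatch bounds (0..2 at the command line).
#' @return data.frame with columns `window_index`, `query_kmer`, `distance`,
#'   `match_kmer`, `match_rendered`, `count`, `locations` (semicolon-joined
#'   `contig:start-end:strand`, 1-based inclusive) and `mismatch_positions`
#'   (comma-joined).
#' @export
detail_windows <- function(index, seq, d_min = 0L, d_max = 2L) {
  stopifnot(inherits(index, "genome_index"))
  win <- .all_windows(seq, index$k)
  out <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    if (win$ambiguous[i]) next
    fm <- fuzzy_query(index, win$code[i], d_min, d_max)
    if (nrow(fm) == 0L) next
    out[[i]] <- data.frame(
      window_index = win$window_index[i],
      query_kmer = win$kmer[i],
      distance = fm$distance,
      match_kmer = fm$match_kmer,
      match_rendered = vapply(fm$match_kmer, dot_notation,
                              query_kmer = win$kmer[i], character(1),
                              USE.NAMES = FALSE),
      count = fm$count,
      locations = vapply(fm$locations, function(l) {
        paste(render_location(l$contig, l$offset, index$k, l$strand),
              collapse = ";")
      }, character(1)),
      mismatch_positions = fm$mismatch_positions,
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(window_index = integer(0), query_kmer = character(0),
                      distance = integer(0), match_kmer = character(0),
                      match_rendered = character(0), count = integer(0),
                      locations = character(0), mismatch_positions = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
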
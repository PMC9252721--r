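# 2-bit k-mer codec. A k-mer over {A,C,G,T} packs into a 64-bit word, two bits
# per base with A=0, C=1, G=2, T=3 and the most significant pair holding the
# 5'-most base, so integer order matches lexicographic order. k is capped at
# 31 so a code occupies at most 62 bits, leaving headroom for tag bits in
# index values. Codes are passed around as decimal strings because codes for
# k > 26 exceed the exact range of a double.

#' Normalise a 64-bit quantity to its decimal-string form
#'
#' K-mer codes and hash values are represented as decimal strings at the R
#' level so that values above 2^53 remain exact. This helper accepts either a
#' non-negative integral numeric below 2^53 or a digit string and returns the
#' canonical string form.
#'
#' @param x numeric or character vector of non-negative integers.
#' @return character vector of decimal digit strings.
#' @export
as_u64 <- function(x) {
  if (is.numeric(x)) {
    if (any(is.na(x)) || any(x < 0) || any(x != trunc(x)))
      fk_stop("parse_error", "numeric u64 values must be non-negative integers")
    if (any(x >= 2^53))
      fk_stop("range_error", "numeric values >= 2^53 are inexact; pass a digit string")
    return(sprintf("%.0f", x))
  }
  x <- as.character(x)
  bad <- !grepl("^[0-9]+$", x)
  if (any(bad))
    fk_stop("parse_error", "not an unsigned integer string: '%s'", x[which(bad)[1]])
  sub("^0+(?=.)", "", x, perl = TRUE)
}

#' Encode a k-mer as a packed integer code
#'
#' @param seq character vector of sequences, each exactly `k` bases over
#'   ACGT (case-insensitive).
#' @param k k-mer length, 1..31.
#' @return character vector of decimal code strings (each `< 4^k`).
#' @examples
#' encode_kmer("ACGT", 4) # "27"
#' @export
encode_kmer <- function(seq, k) {
  wrap_cpp(cpp_encode_kmer(as.character(seq), as.integer(k)))
}

#' Decode a packed k-mer code back to its sequence
#'
#' Exact inverse of [encode_kmer()].
#'
#' @param code code string(s) (or numerics below 2^53).
#' @param k k-mer length.
#' @return character vector of ACGT sequences.
#' @export
decode_kmer <- function(code, k) {
  wrap_cpp(cpp_decode_kmer(as_u64(code), as.integer(k)))
}

#' Reverse-complement a packed k-mer code
#'
#' An involution: `revcomp_code(revcomp_code(x, k), k) == x`.
#'
#' @inheritParams decode_kmer
#' @return character vector of code strings.
#' @export
revcomp_code <- function(code, k) {
  wrap_cpp(cpp_revcomp_code(as_u64(code), as.integer(k)))
}

#' Enumerate sliding k-mer windows over a sequence
#'
#' Decomposes `seq` into its constituent k-mers in sliding-window fashion.
#' Windows containing any non-ACGT character (N or IUPAC codes) are skipped;
#' lower-case (soft-masked) bases are treated as their upper-case
#' equivalents.
#'
#' @param seq a single DNA string.
#' @param k k-mer length.
#' @return data.frame with columns `offset` (0-based window start, ascending),
#'   `code` (decimal code string) and `kmer` (upper-case sequence). Empty when
#'   `nchar(seq) < k`.
#' @export
kmer_windows <- function(seq, k) {
  stopifnot(length(seq) == 1L)
  w <- wrap_cpp(cpp_windows(as.character(seq), as.integer(k)))
  data.frame(
    offset = as.integer(w$offset),
    code = w$code,
    kmer = if (length(w$code)) decode_kmer(w$code, k) else character(0),
    stringsAsFactors = FALSE
  )
}

#' Hamming distance between two k-mer codes
#'
#' @param code_a,code_b code strings (or sequences of length `k`, which are
#'   encoded first).
#' @param k k-mer length.
#' @return list with `distance` (integer) and `positions` (ascending 1-based
#'   mismatch positions counted from the 5' end).
#' @export
kmer_hamming <- function(code_a, code_b, k) {
  code_a <- .as_code(code_a, k)
  code_b <- .as_code(code_b, k)
  wrap_cpp(cpp_hamming(code_a, code_b, as.integer(k)))
}

# accept either a code (digits / numeric) or a raw sequence
.as_code <- function(x, k) {
  if (is.character(x) && length(x) == 1L && grepl("^[ACGTacgt]+$", x) &&
      nchar(x) == k && !grepl("^[0-9]+$", x)) {
    return(encode_kmer(x, k))
  }
  as_u64(x)
}

#' Enumerate the Hamming neighborhood of a k-mer
#'
#' Yields every code at substitution distance in `[d_min, d_max]` of `code`,
#' each exactly once; the code itself is included iff `d_min == 0`. The
#' neighborhood size for distances 1..2 is `3k + 9*choose(k, 2)` (2775 for
#' k = 25).
#'
#' @param code code string or sequence.
#' @param k k-mer length.
#' @param d_min,d_max distance bounds, `0 <= d_min <= d_max <= k`.
#' @return data.frame with columns `code`, `distance` and `positions`
#'   (comma-joined 1-based substituted positions).
#' @export
kmer_neighbors <- function(code, k, d_min = 0L, d_max = 2L) {
  n <- wrap_cpp(cpp_neighbors(.as_code(code, k), as.integer(k),
                              as.integer(d_min), as.integer(d_max)))
  data.frame(code = n$code, distance = n$distance, positions = n$positions,
             stringsAsFactors = FALSE)
}

#' Dot-notation rendering of a match against a query
#'
#' Identical nucleotides are shown as a dot and differing nucleotides as the
#' match k-mer's base at that position, the conventional display for fuzzy
#' k-mer hits.
#'
#' @param query_kmer,match_kmer equal-length sequences.
#' @return a single rendering string.
#' @examples
#' dot_notation("ACGTA", "ACCTA") # "..C.."
#' @export
dot_notation <- function(query_kmer, match_kmer) {
  q <- strsplit(toupper(query_kmer), "")[[1]]
  m <- strsplit(toupper(match_kmer), "")[[1]]
  if (length(q) != length(m))
    fk_stop("length_error", "query and match k-mers differ in length (%d vs %d)",
            length(q), length(m))
  paste(ifelse(q == m, ".", m), collapse = "")
}
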
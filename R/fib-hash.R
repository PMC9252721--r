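# Invertible Fibonacci hash table. Keys are scrambled by multiplication with
# the odd constant nearest 2^64 / phi; because the multiplier is odd it is a
# bijection mod 2^64 and has a modular inverse, so a slot's home bucket (the
# top b bits of the hash) plus its stored remainder (the low 64 - b bits)
# reconstruct the full hash and hence the key. Slots therefore store only
# 1 + 8 + (64 - b) bits of metadata (occupied flag, linear-probe
# displacement, remainder); 64-bit values live in a parallel array.

#' Fibonacci hash of 64-bit values
#'
#' Multiplies by the canonical Fibonacci-hashing constant
#' `0x9E3779B97F4A7C15` modulo 2^64. Bijective, hence invertible by
#' [fib_unmix()].
#'
#' @param x numeric or digit-string vector of unsigned 64-bit values.
#' @return character vector of hashed values as decimal strings.
#' @export
fib_mix <- function(x) wrap_cpp(cpp_fib_mix(as_u64(x)))

#' Invert the Fibonacci hash
#'
#' Multiplies by the modular inverse of the multiplier mod 2^64, so
#' `fib_unmix(fib_mix(x)) == x` for every 64-bit `x`.
#'
#' @inheritParams fib_mix
#' @return character vector of decimal strings.
#' @export
fib_unmix <- function(x) wrap_cpp(cpp_fib_unmix(as_u64(x)))

#' The multiplier and its modular inverse
#'
#' @return named character vector with `multiplier` and `multiplier_inverse`,
#'   satisfying `(multiplier * multiplier_inverse) mod 2^64 == 1`.
#' @export
fib_constants <- function() cpp_fib_constants()

#' Create an empty Fibonacci hash table
#'
#' An open-addressing, build-once/query-many table with linear probing and
#' quotient-style bitpacked slot metadata. Displacements are capped at 254;
#' exceeding the cap or the load factor triggers capacity doubling, which
#' rebuilds by re-inserting keys reconstructed via the inverse hash.
#' Deletion is not supported.
#'
#' @param b log2 of the initial capacity (default 16, i.e. 65536 slots).
#' @param max_load maximum load factor before growth (default 0.7).
#' @return an object of class `fib_table`.
#' @export
fib_table <- function(b = 16L, max_load = 0.7) {
  ptr <- wrap_cpp(cpp_ht_new(as.integer(b), max_load))
  structure(list(ptr = ptr), class = "fib_table")
}

#' Insert key/value pairs into a hash table
#'
#' Keys must be below 2^63 (the top bit is reserved). Re-inserting an
#' existing key replaces its value. The table is modified in place.
#'
#' @param table a [fib_table()].
#' @param keys,values numeric or digit-string vectors of equal length.
#' @return the table, invisibly.
#' @export
ht_insert <- function(table, keys, values) {
  stopifnot(inherits(table, "fib_table"))
  wrap_cpp(cpp_ht_insert(table$ptr, as_u64(keys), as_u64(values)))
  invisible(table)
}

#' Look up keys in a hash table
#'
#' Probes linearly from each key's home bucket, stopping at the first empty
#' slot. Expected cost is constant at bounded load factor.
#'
#' @param table a [fib_table()].
#' @param keys numeric or digit-string vector.
#' @return character vector of values (decimal strings), `NA` where absent.
#' @export
ht_lookup <- function(table, keys) {
  stopifnot(inherits(table, "fib_table"))
  wrap_cpp(cpp_ht_lookup(table$ptr, as_u64(keys)))
}

#' Enumerate the contents of a hash table
#'
#' Keys are reconstructed by inverting the hash from each occupied slot's
#' home bucket and remainder; they are never stored verbatim.
#'
#' @param table a [fib_table()].
#' @return data.frame with `key` and `value` decimal-string columns, one row
#'   per occupied slot, in slot order.
#' @export
ht_keys <- function(table) {
  stopifnot(inherits(table, "fib_table"))
  kv <- cpp_ht_keys(table$ptr)
  data.frame(key = kv$key, value = kv$value, stringsAsFactors = FALSE)
}

#' Hash-table size and layout statistics
#'
#' @param table a [fib_table()].
#' @return list with `b`, `capacity`, `n_keys`, `max_load`, `bits_per_slot`
#'   (`1 + 8 + (64 - b)`) and the backing array sizes.
#' @export
ht_stats <- function(table) {
  stopifnot(inherits(table, "fib_table"))
  cpp_ht_stats(table$ptr)
}

#' Probe instrumentation counters
#'
#' Cumulative lookup calls and slot probes since creation or the last
#' [ht_reset_counters()]; used to verify the constant-expected-time contract.
#'
#' @param table a [fib_table()].
#' @return list with `lookups` and `probes`.
#' @export
ht_counters <- function(table) {
  stopifnot(inherits(table, "fib_table"))
  cpp_ht_counters(table$ptr)
}

#' @rdname ht_counters
#' @export
ht_reset_counters <- function(table) {
  stopifnot(inherits(table, "fib_table"))
  cpp_ht_reset_counters(table$ptr)
  invisible(table)
}

#' Home bucket of a key
#'
#' The top `b` bits of the key's Fibonacci hash — the bucket linear probing
#' starts from in a table of 2^b slots.
#'
#' @param key numeric or digit-string value.
#' @param b log2 of the table capacity.
#' @return numeric bucket index in `[0, 2^b)`.
#' @export
ht_home_bucket <- function(key, b) {
  wrap_cpp(cpp_ht_home_bucket(as_u64(key), as.integer(b)))
}

#' @export
print.fib_table <- function(x, ...) {
  s <- ht_stats(x)
  cat(sprintf("<fib_table> b=%d capacity=%s keys=%s load=%.3f (%d bits/slot)\n",
              s$b, format(s$capacity, big.mark = ","),
              format(s$n_keys, big.mark = ","),
              s$n_keys / s$capacity, s$bits_per_slot))
  invisible(x)
}
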
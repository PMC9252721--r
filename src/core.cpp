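// Core engine: 2-bit k-mer codec, invertible Fibonacci hash table with
// quotient-style bitpacked slots, genome index with posting arena, and
// Hamming-neighborhood fuzzy query.
//
// All 64-bit quantities cross the R boundary as decimal strings so that
// codes for k in 27..31 (which exceed 2^53) stay exact.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const uint64_t FIB_MULT = 0x9E3779B97F4A7C15ULL; // odd integer nearest 2^64/phi
static const uint64_t FIB_INV  = 0xF1DE83E19937733DULL; // modular inverse of FIB_MULT mod 2^64

// ---------------------------------------------------------------- u64 <-> R

static uint64_t parse_u64(const std::string& s) {
  if (s.empty()) stop("ParseError: empty unsigned integer string");
  uint64_t v = 0;
  for (char c : s) {
    if (c < '0' || c > '9') stop("ParseError: invalid unsigned integer '%s'", s.c_str());
    uint64_t d = (uint64_t)(c - '0');
    if (v > (UINT64_MAX - d) / 10) stop("RangeError: unsigned integer overflow in '%s'", s.c_str());
    v = v * 10 + d;
  }
  return v;
}

static std::string u64_str(uint64_t v) { return std::to_string(v); }

static std::vector<uint64_t> parse_u64_vec(const CharacterVector& x) {
  std::vector<uint64_t> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = parse_u64(as<std::string>(x[i]));
  return out;
}

static CharacterVector u64_chr(const std::vector<uint64_t>& v) {
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = u64_str(v[i]);
  return out;
}

// ---------------------------------------------------------------- codec

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t kmer_mask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

static void check_k(int k) {
  if (k < 1 || k > 31) stop("RangeError: k must be in 1..31 (got %d)", k);
}

static void check_code(uint64_t code, int k) {
  check_k(k);
  if (k < 32 && code > kmer_mask(k))
    stop("RangeError: code %s out of range for k=%d", u64_str(code).c_str(), k);
}

static uint64_t encode_one(const std::string& s, int k) {
  if ((int)s.size() != k)
    stop("LengthError: sequence length %d != k=%d", (int)s.size(), k);
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0)
      stop("AmbiguousBaseError: non-ACGT character '%c' at position %d", s[i], i + 1);
    code = (code << 2) | (uint64_t)b;
  }
  return code;
}

static std::string decode_one(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = 0; i < k; ++i)
    s[i] = BITS2BASE[(code >> (2 * (k - 1 - i))) & 3ULL];
  return s;
}

static uint64_t revcomp_one(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    uint64_t b = (code >> (2 * i)) & 3ULL;
    rc = (rc << 2) | (3ULL - b); // complement: A<->T, C<->G is 3 - b
  }
  return rc;
}

// [[Rcpp::export]]
CharacterVector cpp_encode_kmer(CharacterVector seqs, int k) {
  check_k(k);
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = u64_str(encode_one(as<std::string>(seqs[i]), k));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmer(CharacterVector codes, int k) {
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = parse_u64(as<std::string>(codes[i]));
    check_code(c, k);
    out[i] = decode_one(c, k);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp_code(CharacterVector codes, int k) {
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = parse_u64(as<std::string>(codes[i]));
    check_code(c, k);
    out[i] = u64_str(revcomp_one(c, k));
  }
  return out;
}

// Sliding windows over a sequence; windows containing non-ACGT are skipped.
// [[Rcpp::export]]
List cpp_windows(std::string seq, int k) {
  check_k(k);
  std::vector<double> offsets;
  std::vector<uint64_t> codes;
  uint64_t mask = kmer_mask(k), code = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      offsets.push_back((double)(i + 1 - k));
      codes.push_back(code);
    }
  }
  return List::create(_["offset"] = wrap(offsets), _["code"] = u64_chr(codes));
}

// [[Rcpp::export]]
List cpp_hamming(std::string code_a, std::string code_b, int k) {
  uint64_t a = parse_u64(code_a), b = parse_u64(code_b);
  check_code(a, k);
  check_code(b, k);
  uint64_t x = a ^ b;
  std::vector<int> pos;
  for (int i = 0; i < k; ++i)
    if ((x >> (2 * (k - 1 - i))) & 3ULL) pos.push_back(i + 1);
  return List::create(_["distance"] = (int)pos.size(), _["positions"] = wrap(pos));
}

// Enumerate all codes at Hamming distance in [d_min, d_max] of `code`.
// Emits (neighbor code, distance, mismatch positions 1-based from the 5' end).
struct NeighborSet {
  std::vector<uint64_t> codes;
  std::vector<int> dist;
  std::vector<std::vector<int>> pos;
};

static void enum_neighbors_rec(uint64_t code, int k, int d_left, int min_pos,
                               int d_done, std::vector<int>& acc, NeighborSet& out,
                               int d_min) {
  if (d_done >= d_min) {
    out.codes.push_back(code);
    out.dist.push_back(d_done);
    out.pos.push_back(acc);
  }
  if (d_left == 0) return;
  for (int i = min_pos; i < k; ++i) {
    int shift = 2 * (k - 1 - i);
    uint64_t orig = (code >> shift) & 3ULL;
    for (uint64_t b = 0; b < 4; ++b) {
      if (b == orig) continue;
      uint64_t nb = (code & ~(3ULL << shift)) | (b << shift);
      acc.push_back(i + 1);
      enum_neighbors_rec(nb, k, d_left - 1, i + 1, d_done + 1, acc, out, d_min);
      acc.pop_back();
    }
  }
}

static NeighborSet enum_neighbors(uint64_t code, int k, int d_min, int d_max) {
  NeighborSet out;
  std::vector<int> acc;
  enum_neighbors_rec(code, k, d_max, 0, 0, acc, out, d_min);
  return out;
}

// [[Rcpp::export]]
List cpp_neighbors(std::string code, int k, int d_min, int d_max) {
  uint64_t c = parse_u64(code);
  check_code(c, k);
  if (d_min < 0 || d_min > d_max || d_max > k)
    stop("RangeError: need 0 <= d_min <= d_max <= k");
  NeighborSet ns = enum_neighbors(c, k, d_min, d_max);
  CharacterVector pos(ns.pos.size());
  for (size_t i = 0; i < ns.pos.size(); ++i) {
    std::string p;
    for (size_t j = 0; j < ns.pos[i].size(); ++j) {
      if (j) p += ",";
      p += std::to_string(ns.pos[i][j]);
    }
    pos[i] = p;
  }
  return List::create(_["code"] = u64_chr(ns.codes),
                      _["distance"] = wrap(ns.dist),
                      _["positions"] = pos);
}

// ---------------------------------------------------------------- Fibonacci mixing

// [[Rcpp::export]]
CharacterVector cpp_fib_mix(CharacterVector x) {
  std::vector<uint64_t> v = parse_u64_vec(x);
  for (auto& e : v) e *= FIB_MULT;
  return u64_chr(v);
}

// [[Rcpp::export]]
CharacterVector cpp_fib_unmix(CharacterVector x) {
  std::vector<uint64_t> v = parse_u64_vec(x);
  for (auto& e : v) e *= FIB_INV;
  return u64_chr(v);
}

// [[Rcpp::export]]
CharacterVector cpp_fib_constants() {
  return CharacterVector::create(_["multiplier"] = u64_str(FIB_MULT),
                                 _["multiplier_inverse"] = u64_str(FIB_INV));
}

// splitmix64: independent stream for bulk randomized self-checks
static inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// mix-then-unmix round trip over n pseudorandom 64-bit values; returns the
// number of values that failed to invert (0 iff the hash is bijective).
// [[Rcpp::export]]
double cpp_fib_roundtrip_check(double n, double seed) {
  uint64_t st = (uint64_t)seed;
  uint64_t bad = 0;
  for (uint64_t i = 0; i < (uint64_t)n; ++i) {
    uint64_t x = splitmix64(st);
    if ((x * FIB_MULT) * FIB_INV != x) ++bad;
  }
  return (double)bad;
}

// [[Rcpp::export]]
CharacterVector cpp_random_u64(double n, double seed) {
  uint64_t st = (uint64_t)seed;
  std::vector<uint64_t> v((size_t)n);
  for (auto& e : v) e = splitmix64(st);
  return u64_chr(v);
}

// ---------------------------------------------------------------- packed bit fields

static inline uint64_t get_field(const std::vector<uint64_t>& v, uint64_t bitpos, int width) {
  uint64_t word = bitpos >> 6;
  int off = (int)(bitpos & 63);
  uint64_t lo = v[word] >> off;
  if (off + width > 64) lo |= v[word + 1] << (64 - off);
  return (width >= 64) ? lo : (lo & ((1ULL << width) - 1ULL));
}

static inline void set_field(std::vector<uint64_t>& v, uint64_t bitpos, int width, uint64_t val) {
  uint64_t word = bitpos >> 6;
  int off = (int)(bitpos & 63);
  uint64_t mask = (width >= 64) ? ~0ULL : ((1ULL << width) - 1ULL);
  val &= mask;
  v[word] = (v[word] & ~(mask << off)) | (val << off);
  if (off + width > 64) {
    int hi = off + width - 64;
    uint64_t hmask = (1ULL << hi) - 1ULL;
    v[word + 1] = (v[word + 1] & ~hmask) | (val >> (64 - off));
  }
}

// ---------------------------------------------------------------- hash table

// Open-addressing table. Slot metadata is a packed record of
// 1 (occupied) + 8 (displacement) + (64 - b) (hash remainder) bits; the home
// bucket is the slot index minus the displacement, so the full 64-bit hash --
// and from it the key, via the inverse multiplier -- is reconstructed rather
// than stored. Values live in a parallel 64-bit array.
struct FibTable {
  int b;              // log2 capacity
  uint64_t cap;       // 2^b
  int r;              // remainder bits = 64 - b
  int w;              // slot record width = 9 + r
  double max_load;
  uint64_t n_keys = 0;
  std::vector<uint64_t> bits;
  std::vector<uint64_t> vals;
  mutable double n_lookups = 0, n_probes = 0;

  FibTable(int b_, double ml) { init(b_, ml); }

  void init(int b_, double ml) {
    if (b_ < 1 || b_ > 62) stop("CapacityError: table size exponent b must be in 1..62");
    b = b_;
    cap = 1ULL << b;
    r = 64 - b;
    w = 9 + r;
    max_load = ml;
    n_keys = 0;
    bits.assign((size_t)((cap * (uint64_t)w + 63) / 64 + 1), 0ULL);
    vals.assign((size_t)cap, 0ULL);
  }

  inline bool occ(uint64_t s) const { return get_field(bits, s * w, 1) != 0; }
  inline uint64_t disp(uint64_t s) const { return get_field(bits, s * w + 1, 8); }
  inline uint64_t rem(uint64_t s) const { return get_field(bits, s * w + 9, r); }
  inline void set_slot(std::vector<uint64_t>& bv, uint64_t s, uint64_t d, uint64_t rm) const {
    set_field(bv, s * w, 1, 1);
    set_field(bv, s * w + 1, 8, d);
    set_field(bv, s * w + 9, r, rm);
  }

  inline uint64_t home_of(uint64_t key) const { return (key * FIB_MULT) >> r; }
  inline uint64_t rem_of(uint64_t key) const {
    return (key * FIB_MULT) & ((r >= 64) ? ~0ULL : ((1ULL << r) - 1ULL));
  }

  uint64_t slot_key(uint64_t s) const {
    uint64_t home = (s - disp(s)) & (cap - 1);
    uint64_t h = (home << r) | rem(s);
    return h * FIB_INV;
  }

  bool lookup(uint64_t key, uint64_t* out) const {
    n_lookups += 1;
    uint64_t home = home_of(key), rm = rem_of(key);
    for (uint64_t d = 0; d < cap; ++d) {
      n_probes += 1;
      uint64_t s = (home + d) & (cap - 1);
      if (!occ(s)) return false;
      if (rem(s) == rm && ((s - disp(s)) & (cap - 1)) == home) {
        if (out) *out = vals[s];
        return true;
      }
    }
    return false;
  }

  // try to place without growing; returns false on displacement overflow
  bool place(uint64_t key, uint64_t val) {
    uint64_t home = home_of(key), rm = rem_of(key);
    for (uint64_t d = 0; d < cap; ++d) {
      uint64_t s = (home + d) & (cap - 1);
      if (!occ(s)) {
        if (d > 254) return false;
        set_slot(bits, s, d, rm);
        vals[s] = val;
        ++n_keys;
        return true;
      }
      if (rem(s) == rm && ((s - disp(s)) & (cap - 1)) == home) {
        vals[s] = val; // re-insert replaces
        return true;
      }
    }
    return false;
  }

  void insert(uint64_t key, uint64_t val) {
    if (key >> 63) stop("RangeError: key must be < 2^63 (top bit reserved)");
    for (;;) {
      if ((double)(n_keys + 1) > max_load * (double)cap) { grow(); continue; }
      if (place(key, val)) return;
      grow();
    }
  }

  void grow() {
    int nb = b + 1;
    for (;;) {
      if (nb > 62) stop("CapacityError: cannot grow table beyond 2^62 slots");
      FibTable nt(nb, max_load);
      if ((double)n_keys > max_load * (double)nt.cap) { ++nb; continue; }
      bool ok = true;
      for (uint64_t s = 0; s < cap && ok; ++s)
        if (occ(s)) ok = nt.place(slot_key(s), vals[s]);
      if (!ok) { ++nb; continue; }
      b = nt.b; cap = nt.cap; r = nt.r; w = nt.w;
      n_keys = nt.n_keys;
      bits.swap(nt.bits);
      vals.swap(nt.vals);
      return;
    }
  }
};

// [[Rcpp::export]]
SEXP cpp_ht_new(int b, double max_load) {
  if (max_load <= 0 || max_load > 0.95) stop("RangeError: max_load must be in (0, 0.95]");
  return XPtr<FibTable>(new FibTable(b, max_load), true);
}

// [[Rcpp::export]]
void cpp_ht_insert(SEXP xp, CharacterVector keys, CharacterVector values) {
  XPtr<FibTable> t(xp);
  if (keys.size() != values.size()) stop("LengthError: keys and values differ in length");
  for (R_xlen_t i = 0; i < keys.size(); ++i)
    t->insert(parse_u64(as<std::string>(keys[i])), parse_u64(as<std::string>(values[i])));
}

// [[Rcpp::export]]
CharacterVector cpp_ht_lookup(SEXP xp, CharacterVector keys) {
  XPtr<FibTable> t(xp);
  CharacterVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    uint64_t v;
    if (t->lookup(parse_u64(as<std::string>(keys[i])), &v)) out[i] = u64_str(v);
    else out[i] = NA_STRING;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_ht_keys(SEXP xp) {
  XPtr<FibTable> t(xp);
  std::vector<uint64_t> k, v;
  k.reserve(t->n_keys);
  v.reserve(t->n_keys);
  for (uint64_t s = 0; s < t->cap; ++s)
    if (t->occ(s)) { k.push_back(t->slot_key(s)); v.push_back(t->vals[s]); }
  return List::create(_["key"] = u64_chr(k), _["value"] = u64_chr(v));
}

// [[Rcpp::export]]
List cpp_ht_stats(SEXP xp) {
  XPtr<FibTable> t(xp);
  return List::create(
    _["b"] = t->b,
    _["capacity"] = (double)t->cap,
    _["n_keys"] = (double)t->n_keys,
    _["max_load"] = t->max_load,
    _["bits_per_slot"] = t->w,
    _["slot_words"] = (double)t->bits.size(),
    _["value_words"] = (double)t->vals.size());
}

// [[Rcpp::export]]
List cpp_ht_counters(SEXP xp) {
  XPtr<FibTable> t(xp);
  return List::create(_["lookups"] = t->n_lookups, _["probes"] = t->n_probes);
}

// [[Rcpp::export]]
void cpp_ht_reset_counters(SEXP xp) {
  XPtr<FibTable> t(xp);
  t->n_lookups = 0;
  t->n_probes = 0;
}

// [[Rcpp::export]]
double cpp_ht_home_bucket(std::string key, int b) {
  if (b < 1 || b > 62) stop("RangeError: b must be in 1..62");
  return (double)((parse_u64(key) * FIB_MULT) >> (64 - b));
}

// ------------------------------------------------- table (de)serialization

static void push_u64(std::vector<uint8_t>& out, uint64_t v) {
  for (int i = 0; i < 8; ++i) out.push_back((uint8_t)(v >> (8 * i)));
}

static uint64_t pull_u64(const uint8_t* p) {
  uint64_t v = 0;
  for (int i = 0; i < 8; ++i) v |= ((uint64_t)p[i]) << (8 * i);
  return v;
}

// little-endian blob: b, n_keys, max_load bits, n slot words, words,
// capacity, values
// [[Rcpp::export]]
RawVector cpp_table_to_blob(SEXP xp) {
  XPtr<FibTable> t(xp);
  std::vector<uint8_t> out;
  out.reserve(16 + 8 * (t->bits.size() + t->vals.size()));
  push_u64(out, (uint64_t)t->b);
  push_u64(out, t->n_keys);
  uint64_t ml;
  std::memcpy(&ml, &t->max_load, 8);
  push_u64(out, ml);
  push_u64(out, (uint64_t)t->bits.size());
  for (uint64_t wd : t->bits) push_u64(out, wd);
  push_u64(out, (uint64_t)t->vals.size());
  for (uint64_t wd : t->vals) push_u64(out, wd);
  RawVector rv(out.size());
  std::memcpy(RAW(rv), out.data(), out.size());
  return rv;
}

// [[Rcpp::export]]
SEXP cpp_table_from_blob(RawVector blob) {
  const uint8_t* p = RAW(blob);
  size_t n = blob.size(), at = 0;
  auto need = [&](size_t bytes) {
    if (at + bytes > n) stop("FormatError: truncated table section");
  };
  need(32);
  uint64_t b = pull_u64(p + at); at += 8;
  uint64_t nk = pull_u64(p + at); at += 8;
  uint64_t mlbits = pull_u64(p + at); at += 8;
  double ml;
  std::memcpy(&ml, &mlbits, 8);
  uint64_t nbits = pull_u64(p + at); at += 8;
  if (b < 1 || b > 62 || !(ml > 0) || ml > 0.95)
    stop("FormatError: corrupt table header");
  XPtr<FibTable> t(new FibTable((int)b, ml), true);
  if (t->bits.size() != nbits) stop("FormatError: slot bitstream size mismatch");
  need(8 * nbits);
  for (uint64_t i = 0; i < nbits; ++i) { t->bits[i] = pull_u64(p + at); at += 8; }
  need(8);
  uint64_t nvals = pull_u64(p + at); at += 8;
  if (nvals != t->cap) stop("FormatError: value array size mismatch");
  need(8 * nvals);
  for (uint64_t i = 0; i < nvals; ++i) { t->vals[i] = pull_u64(p + at); at += 8; }
  if (at != n) stop("FormatError: trailing bytes in table section");
  t->n_keys = nk;
  return t;
}

// FNV-1a over raw bytes, reported as decimal string (used for the contig
// table and whole-file checksums).
// [[Rcpp::export]]
std::string cpp_fnv1a(RawVector bytes) {
  uint64_t h = 0xCBF29CE484222325ULL;
  const uint8_t* p = RAW(bytes);
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)p[i];
    h *= 0x100000001B3ULL;
  }
  return u64_str(h);
}

// [[Rcpp::export]]
RawVector cpp_u64_to_raw(CharacterVector x) {
  std::vector<uint8_t> out;
  out.reserve(8 * x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) push_u64(out, parse_u64(as<std::string>(x[i])));
  RawVector rv(out.size());
  if (!out.empty()) std::memcpy(RAW(rv), out.data(), out.size());
  return rv;
}

// [[Rcpp::export]]
CharacterVector cpp_raw_to_u64(RawVector bytes) {
  if (bytes.size() % 8 != 0) stop("FormatError: raw length not a multiple of 8");
  std::vector<uint64_t> v(bytes.size() / 8);
  for (size_t i = 0; i < v.size(); ++i) v[i] = pull_u64(RAW(bytes) + 8 * i);
  return u64_chr(v);
}

// ---------------------------------------------------------------- genome index

// Location packs (contig ordinal: 16 bits, 0-based offset: 46 bits,
// strand: 1 bit) into 63 bits; bit 0 of a table value tags inline location
// (0) versus posting-arena offset (1).
struct GenomeIdx {
  int k;
  int both; // strand mode: 0 forward, 1 both
  FibTable table;
  std::vector<uint64_t> arena;
  std::vector<std::string> contig_names;
  std::vector<uint64_t> contig_lengths;
  GenomeIdx(int b0, double ml) : k(0), both(0), table(b0, ml) {}
};

static const uint64_t PENDING_INLINE = ~0ULL;

static inline uint64_t pack_loc(uint64_t ord, uint64_t off, int strand_minus) {
  return (ord << 47) | (off << 1) | (uint64_t)strand_minus;
}

struct Loc { uint32_t ord; uint64_t off; int strand_minus; };

static inline Loc unpack_loc(uint64_t v) {
  Loc l;
  l.ord = (uint32_t)(v >> 47);
  l.off = (v >> 1) & ((1ULL << 46) - 1ULL);
  l.strand_minus = (int)(v & 1ULL);
  return l;
}

template <typename F>
static void for_each_window(const std::string& seq, int k, F&& fn) {
  uint64_t mask = kmer_mask(k), code = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) fn((uint64_t)(i + 1 - k), code);
  }
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector contigs, int k, int both, int b0, double max_load) {
  check_k(k);
  if (contigs.size() == 0) stop("EmptyInputError: no contigs supplied");
  if (contigs.size() > 65535) stop("RangeError: more than 2^16 contigs");
  CharacterVector nm = contigs.names();
  if (nm.isNULL()) stop("EmptyInputError: contigs must be named");
  XPtr<GenomeIdx> gi(new GenomeIdx(b0, max_load), true);
  gi->k = k;
  gi->both = both;
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    std::string name = as<std::string>(nm[ci]);
    std::string seq = as<std::string>(contigs[ci]);
    for (const auto& existing : gi->contig_names)
      if (existing == name) stop("DuplicateContigNameError: contig '%s' repeated", name.c_str());
    if ((uint64_t)seq.size() >= (1ULL << 46)) stop("RangeError: contig longer than 2^46");
    gi->contig_names.push_back(name);
    gi->contig_lengths.push_back((uint64_t)seq.size());
  }
  FibTable& t = gi->table;
  // pass 1: counts
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    std::string seq = as<std::string>(contigs[ci]);
    for_each_window(seq, k, [&](uint64_t, uint64_t code) {
      uint64_t v;
      if (t.lookup(code, &v)) t.insert(code, v + 1);
      else t.insert(code, 1);
    });
  }
  // allocate arena entries; singletons become pending inline
  uint64_t arena_size = 0;
  for (uint64_t s = 0; s < t.cap; ++s)
    if (t.occ(s) && t.vals[s] >= 2) arena_size += t.vals[s] + 1;
  gi->arena.assign((size_t)arena_size, 0ULL);
  uint64_t next = 0;
  for (uint64_t s = 0; s < t.cap; ++s) {
    if (!t.occ(s)) continue;
    uint64_t c = t.vals[s];
    if (c == 1) {
      t.vals[s] = PENDING_INLINE;
    } else {
      t.vals[s] = (next << 1) | 1ULL;
      gi->arena[(size_t)next] = next + 1; // fill cursor
      next += c + 1;
    }
  }
  // pass 2: locations
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    std::string seq = as<std::string>(contigs[ci]);
    for_each_window(seq, k, [&](uint64_t off, uint64_t code) {
      uint64_t loc = pack_loc((uint64_t)ci, off, 0);
      uint64_t v;
      if (!t.lookup(code, &v)) stop("internal error: key vanished between passes");
      if (v == PENDING_INLINE) {
        t.insert(code, loc << 1);
      } else if (v & 1ULL) {
        uint64_t head = v >> 1;
        uint64_t cur = gi->arena[(size_t)head];
        gi->arena[(size_t)cur] = loc;
        gi->arena[(size_t)head] = cur + 1;
      } else {
        stop("internal error: singleton key seen twice");
      }
    });
  }
  // normalize cursors back to counts
  for (uint64_t s = 0; s < t.cap; ++s) {
    if (!t.occ(s)) continue;
    uint64_t v = t.vals[s];
    if (v & 1ULL) {
      uint64_t head = v >> 1;
      gi->arena[(size_t)head] = gi->arena[(size_t)head] - head - 1;
    }
  }
  t.n_lookups = 0;
  t.n_probes = 0;
  return gi;
}

static void collect_locs(const GenomeIdx& gi, uint64_t code, int strand_minus,
                         std::vector<uint64_t>& locs) {
  uint64_t v;
  if (!gi.table.lookup(code, &v)) return;
  if (v & 1ULL) {
    uint64_t head = v >> 1;
    uint64_t c = gi.arena[(size_t)head];
    for (uint64_t i = 0; i < c; ++i)
      locs.push_back((gi.arena[(size_t)(head + 1 + i)] & ~1ULL) | (uint64_t)strand_minus);
  } else {
    locs.push_back((v >> 1 & ~1ULL) | (uint64_t)strand_minus);
  }
}

// query one code; honours strand mode (reverse-complement hits get strand '-')
static void query_code(const GenomeIdx& gi, uint64_t code, std::vector<uint64_t>& locs) {
  collect_locs(gi, code, 0, locs);
  if (gi.both) {
    uint64_t rc = revcomp_one(code, gi.k);
    if (rc != code) collect_locs(gi, rc, 1, locs);
  }
}

static List locs_to_list(const std::vector<uint64_t>& locs) {
  IntegerVector ord((R_xlen_t)locs.size());
  NumericVector off((R_xlen_t)locs.size());
  CharacterVector strand((R_xlen_t)locs.size());
  for (size_t i = 0; i < locs.size(); ++i) {
    Loc l = unpack_loc(locs[i]);
    ord[i] = (int)l.ord + 1;
    off[i] = (double)l.off;
    strand[i] = l.strand_minus ? "-" : "+";
  }
  return List::create(_["contig_ord"] = ord, _["offset"] = off, _["strand"] = strand);
}

// [[Rcpp::export]]
List cpp_index_exact_query(SEXP xp, std::string code) {
  XPtr<GenomeIdx> gi(xp);
  uint64_t c = parse_u64(code);
  check_code(c, gi->k);
  std::vector<uint64_t> locs;
  query_code(*gi, c, locs);
  return List::create(_["count"] = (double)locs.size(), _["locations"] = locs_to_list(locs));
}

// [[Rcpp::export]]
List cpp_index_fuzzy_query(SEXP xp, std::string code, int d_min, int d_max) {
  XPtr<GenomeIdx> gi(xp);
  uint64_t c = parse_u64(code);
  check_code(c, gi->k);
  if (d_min < 0 || d_min > d_max || d_max > gi->k)
    stop("RangeError: need 0 <= d_min <= d_max <= k");
  NeighborSet ns = enum_neighbors(c, gi->k, d_min, d_max);
  // sort neighbor candidates by (distance, code)
  std::vector<size_t> ord(ns.codes.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b2) {
    if (ns.dist[a] != ns.dist[b2]) return ns.dist[a] < ns.dist[b2];
    return ns.codes[a] < ns.codes[b2];
  });
  std::vector<uint64_t> m_code;
  std::vector<int> m_dist;
  std::vector<std::string> m_pos;
  std::vector<double> m_count;
  std::vector<int> l_match;
  std::vector<uint64_t> l_loc;
  for (size_t oi = 0; oi < ord.size(); ++oi) {
    size_t i = ord[oi];
    std::vector<uint64_t> locs;
    query_code(*gi, ns.codes[i], locs);
    if (locs.empty()) continue;
    m_code.push_back(ns.codes[i]);
    m_dist.push_back(ns.dist[i]);
    std::string p;
    for (size_t j = 0; j < ns.pos[i].size(); ++j) {
      if (j) p += ",";
      p += std::to_string(ns.pos[i][j]);
    }
    m_pos.push_back(p);
    m_count.push_back((double)locs.size());
    for (uint64_t lc : locs) {
      l_match.push_back((int)m_code.size());
      l_loc.push_back(lc);
    }
  }
  List locl = locs_to_list(l_loc);
  locl["match"] = wrap(l_match);
  return List::create(
    _["match_code"] = u64_chr(m_code),
    _["distance"] = wrap(m_dist),
    _["positions"] = wrap(m_pos),
    _["count"] = wrap(m_count),
    _["locations"] = locl);
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<GenomeIdx> gi(xp);
  double total = 0, distinct = 0;
  FibTable& t = gi->table;
  for (uint64_t s = 0; s < t.cap; ++s) {
    if (!t.occ(s)) continue;
    distinct += 1;
    uint64_t v = t.vals[s];
    total += (v & 1ULL) ? (double)gi->arena[(size_t)(v >> 1)] : 1.0;
  }
  return List::create(
    _["k"] = gi->k,
    _["strand_mode"] = gi->both ? "both" : "forward",
    _["n_distinct"] = distinct,
    _["n_windows"] = total,
    _["contig_names"] = wrap(gi->contig_names),
    _["contig_lengths"] = wrap(std::vector<double>(gi->contig_lengths.begin(),
                                                   gi->contig_lengths.end())),
    _["table_b"] = t.b,
    _["table_capacity"] = (double)t.cap,
    _["bits_per_slot"] = t.w,
    _["arena_words"] = (double)gi->arena.size());
}

// [[Rcpp::export]]
List cpp_index_counters(SEXP xp) {
  XPtr<GenomeIdx> gi(xp);
  return List::create(_["lookups"] = gi->table.n_lookups, _["probes"] = gi->table.n_probes);
}

// [[Rcpp::export]]
void cpp_index_reset_counters(SEXP xp) {
  XPtr<GenomeIdx> gi(xp);
  gi->table.n_lookups = 0;
  gi->table.n_probes = 0;
}

// [[Rcpp::export]]
RawVector cpp_arena_to_raw(SEXP xp) {
  XPtr<GenomeIdx> gi(xp);
  std::vector<uint8_t> out;
  out.reserve(8 + 8 * gi->arena.size());
  push_u64(out, (uint64_t)gi->arena.size());
  for (uint64_t w : gi->arena) push_u64(out, w);
  RawVector rv(out.size());
  std::memcpy(RAW(rv), out.data(), out.size());
  return rv;
}

// [[Rcpp::export]]
RawVector cpp_index_table_blob(SEXP xp) {
  XPtr<GenomeIdx> gi(xp);
  // reuse table serializer through a temporary external pointer view
  XPtr<FibTable> tv(&gi->table, false);
  return cpp_table_to_blob(tv);
}

// [[Rcpp::export]]
SEXP cpp_index_from_blobs(RawVector table_blob, RawVector arena_raw, int k, int both,
                          CharacterVector contig_names, NumericVector contig_lengths) {
  check_k(k);
  XPtr<FibTable> t(cpp_table_from_blob(table_blob));
  XPtr<GenomeIdx> gi(new GenomeIdx(1, t->max_load), true);
  gi->k = k;
  gi->both = both;
  gi->table = *t;
  const uint8_t* p = RAW(arena_raw);
  if (arena_raw.size() < 8) stop("FormatError: truncated arena section");
  uint64_t n = pull_u64(p);
  if ((uint64_t)arena_raw.size() != 8 + 8 * n) stop("FormatError: arena size mismatch");
  gi->arena.resize((size_t)n);
  for (uint64_t i = 0; i < n; ++i) gi->arena[(size_t)i] = pull_u64(p + 8 + 8 * i);
  for (R_xlen_t i = 0; i < contig_names.size(); ++i) {
    gi->contig_names.push_back(as<std::string>(contig_names[i]));
    gi->contig_lengths.push_back((uint64_t)contig_lengths[i]);
  }
  return gi;
}
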
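---
title: "Methods: invertible-hash k-mer indexing and fuzzy search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invertible-hash k-mer indexing and fuzzy search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibkmer)
```

## The model

`fibkmer` indexes a genome assembly as the multiset of its k-mers. Every
window of every contig whose k bases are all in {A,C,G,T} is a key; its
value records how often the window occurs and at which (contig, offset,
strand) locations. Queries decompose an input sequence into its constituent
k-mers in sliding-window fashion and look each window up — exactly, or
fuzzily within a Hamming ball of radius ≤ 2.

Three design commitments shape everything else:

1. **Indices are built rarely and queried often.** Construction cost is
   secondary; per-query latency is the target. Deletion is unsupported.
2. **Search must be comprehensive.** Every k-mer of the assembly is
   indexed, so a unique k-mer can never be missed the way seed-based
   aligners (which pre-filter with short seeds) can miss queries whose
   seeds are over-represented.
3. **Lookups must cost O(1)** in both k and assembly length, so that a
   fuzzy query's cost is purely a function of its neighborhood size.

## The hash table

### Encoding

A k-mer packs 2 bits/base (A=0 < C=1 < G=2 < T=3, alphabetical so integer
order equals lexicographic order), 5'-most base in the most significant
pair. k is capped at 31 so a code fits 62 bits of a 64-bit word, leaving
room for tag bits. Lower-case (soft-masked) input is upper-cased; any other
character invalidates the window containing it rather than erroring the
whole sequence — window indices in reports stay aligned with query
coordinates, with ambiguous windows flagged.

At the R interface 64-bit quantities travel as decimal strings, since codes
for k ≥ 27 exceed the exact integer range of a double. Helpers accept plain
numerics below 2^53.

### Invertible Fibonacci hashing

Keys are hashed by multiplication modulo 2⁶⁴ with
`M = 0x9E3779B97F4A7C15`, the odd integer nearest 2⁶⁴/φ — the classical
Fibonacci-hashing constant, chosen because consecutive keys scatter across
buckets and the high bits of the product are the well-mixed ones. Because M
is odd it has a modular inverse M⁻¹ mod 2⁶⁴ (`17428512612931826493`,
verified in the tests against an independently computed extended-Euclid
value), making the hash a bijection.

### Quotient-style bitpacking

A table of capacity 2^b derives, from each 64-bit hash h:

* the **home bucket** — the top b bits of h;
* the **remainder** — the low 64 − b bits.

An occupied slot stores 1 occupancy bit, an 8-bit linear-probe
displacement (slot index − home bucket, mod capacity), and the remainder:
`1 + 8 + (64 − b)` bits per slot, packed contiguously in a bitstream.
Since (home, remainder) determine h completely and the hash is bijective,
equality tests are exact — this is a hash table, not a filter; there are no
false positives — and any slot's key can be reconstructed as
`M⁻¹ · ((home << (64−b)) | remainder)`. Iteration, growth and
serialization all rely on reconstruction; keys are never materialized in
memory or on disk.

Collisions resolve by linear probing: insertion scans from the home bucket
to the first empty slot; lookup scans until a slot matches (same home and
remainder) or an empty slot proves absence. Growth doubles capacity and
re-inserts reconstructed keys; it triggers when the load factor would
exceed 0.7 — past which linear-probe clusters grow quickly — or when a
displacement would exceed 254, the largest value the 8-bit field holds with
margin. The default initial capacity is 2^16 slots, sized so that toy and
bacterial-scale builds never grow more than a handful of times; any
starting `b` can be given.

Values are a parallel array of 64-bit payloads. For a genome index the low
bit tags the payload: 0 — a single location inlined in the upper 63 bits
(16-bit contig ordinal, 46-bit offset, 1-bit strand); 1 — an offset into an
append-only posting arena whose entry is a count followed by that many
packed locations. Singletons — the vast majority of k-mers in real genomes
at k ≥ 19 — therefore cost no arena space, and counts are unbounded.

### Strand convention

By default indexing is **forward-only**: locations are positions of the
k-mer as written in the FASTA. `strand_mode = "both"` matches
reverse-complement occurrences at query time (reported with strand `-`)
instead of doubling the index; a palindromic query is reported once, on the
forward strand. Query-time matching was chosen over canonical-form indexing
so that forward-mode counts remain exact occurrence counts of the literal
string, which is what the count-conservation invariant (Σ counts = number
of valid windows) audits.

## Fuzzy search

A fuzzy query at distances d_min..d_max enumerates the query's entire
Hamming neighborhood — `Σ_d 3^d C(k,d)` codes, at most 1 + 93 + 4185 = 4279
for k = 31, d ≤ 2 — and performs one exact lookup per neighbor. Full
enumeration was preferred to seed-partition schemes because each lookup is
O(1): the budget is a closed form, independent of genome size, which the
instrumented probe counters verify at run time. Distances are
substitution-only (mismatches); insertion/deletion edits of the query are
out of scope, which is why the CLI caps d at 2 where the neighborhood stays
small.

Reports come in two shapes. The **summary** gives, per query window, the
number of genome *locations* matched at each distance (0, 1, 2) — counting
locations rather than distinct neighbor sequences, so a repeat-heavy match
inflates the count the way an off-target screen should see it. The
**detail** lists each matching neighbor sequence with its count, its
locations rendered 1-based inclusive (`contig:start-end:strand`), the
1-based mismatch positions, and a dot-notation rendering in which identical
bases print as `.` and differing bases print as the match's base. Detail
output truncates at `max_detail_rows` (default 1000) with the overflow
written to a sidecar file; the summary is computed before truncation and is
never affected by it.

## Variants as k-mers

A variant is represented by the k-mers of its **alternate haplotype**: the
ALT allele embedded in up to k − 1 reference bases on each side of the
altered interval, clipped at contig edges. VCF-style left-anchored indels
share their first base between REF and ALT; the anchor counts as context,
not altered sequence. The k-mers kept are the windows overlapping the
altered interval — for a deletion, whose altered interval is a zero-length
junction, the windows containing both junction-adjacent bases. With full
context the counts are exactly k (SNV), k − 1 (deletion), and L + k − 1
(insertion of L bases); multi-base substitutions follow the same rule with
L_alt = ALT length.

Indexing a catalogue of variants this way yields a bipartite graph: codes
on one side, variant records (coordinate, alleles, type, a configurable
ordered list of allele-frequency INFO keys) on the other. A code shared by
several variants maps to all of them. Variant k-mers that also occur in the
reference assembly are *flagged* rather than silently dropped (dropping is
opt-in), because the graph should stay faithful to the catalogue: for
substitutions a variant k-mer can never equal the reference window it
replaces, but an indel in a low-complexity context — a deletion inside a
homopolymer, say — legitimately reproduces reference k-mers, and a query
should be told so. Overlapping variants are treated independently, one
alternate haplotype per record; compound haplotypes are out of scope.

Records whose REF allele contradicts the reference are logged, counted and
skipped rather than aborting the build, and construction is order-
independent, so an unsorted VCF builds the same index.

## Serialization

Indices persist in a little-endian container: magic `KMKY`, format version,
k, strand mode, the contig table, a checksum of the contig table (names,
lengths and per-contig sequence digests — so a coordinate query can verify
that the FASTA it is handed matches the index), the packed slot-metadata
bitstream and value array exactly as held in memory, the posting arena, and
a whole-file FNV-1a checksum. Variant indices share the container with a
record-store section (bipartite entries plus the variant metadata table).
Loading verifies magic, version and checksums before reconstructing, and a
loaded index answers every query identically to the saved one — a property
the tests check exhaustively on small indices and by sampling on larger
ones.

## The simulators and the oracle

`simulate_genome()` emulates the one feature of real assemblies this method
is sensitive to: **approximate repeats**. It generates i.i.d. bases at a
configurable GC fraction (default 0.41, human-like) and plants copies of
source k-mers mutated at exactly the requested positions, recording every
planting in a truth table. Plantings are non-overlapping so truth counting
is unambiguous. `simulate_variants()` places SNVs and indels at loci with
full flanking context and no mutual overlap, REF alleles read from the
genome, with uniform allele frequencies per requested INFO key. Both are
deterministic under their seed and restore the caller's RNG state.

What the simulations do *not* emulate: long-range repeat structure
(segmental duplications, satellite arrays), N-runs and assembly gaps,
biased base composition along chromosomes, or clustered/overlapping
variants. Passing tests therefore demonstrate the correctness of the data
structure and search — which is what they audit — not robustness of any
biological interpretation on real genomes; on real data the same code paths
run, only with heavier posting lists.

Ground truth for every search result is `naive_fuzzy_scan()`: a direct
character-by-character Hamming scan of every genome window, implemented
with string comparison only — no codec, no hashing, no shared code with the
index — so agreement between the two routes is evidence, not tautology.

## Numerical and degenerate-input choices

* Mismatch positions are 1-based from the 5' end, matching how a biologist
  reads "a mismatch at the 3rd base".
* User-facing coordinates are 1-based inclusive (`contig:start-end`, ASCII
  hyphen or pasted en-dash both accepted); everything internal is 0-based
  half-open. Inverted intervals and thousands separators are rejected.
* Queries shorter than k return empty results, not errors; windows
  containing non-ACGT characters yield flagged summary rows and no detail
  rows.
* Keys are required below 2^63 (top bit reserved for future tagging);
  k-mer codes at k ≤ 31 occupy at most 62 bits, far inside the bound.
* Table capacities are powers of two up to 2^62; growth failure past that
  is a capacity error, unreachable at any realistic scale.

## Problem sizes in the checks

The shipped verification uses 10 kb genomes (20 of them, seeds 1..20, with
planted repeats at distances 1–2) queried at k ∈ {11, 19, 25, 31} against
the brute-force oracle; 10^5-value hash-inversion and 10^5-key
insert/lookup workloads against an environment-based reference map; ~10^3
planted variants for the count law across k ∈ {11, 21, 31}; and ~10^2
regions/queries for the pipeline identities. These sizes exercise every
growth, arena and truncation path (the A/T-only truncation fixture forces
> 1000 detail rows) while a full run stays in the minutes range on one
core. The acceptance script re-runs scaled versions of the same
computations from scratch under a caller-supplied seed.

## Known limitations

* Substitution-only fuzzy search; no indel-tolerant matching of queries.
* d ≤ 2 at the CLI; the library accepts larger radii but the neighborhood
  grows as 3^d C(k,d).
* No minimizers, spaced seeds, or k > 31 multi-word codes.
* Indices are in-memory at query time; no memory mapping.
* One alternate haplotype per variant record; nearby variants do not
  compose.
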
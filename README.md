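# fibkmer

Fuzzy k-mer indexing of genome assemblies and variant catalogues in R.

`fibkmer` answers the question "where — and how uniquely — does this short
sequence occur in an assembly?" for anyone designing primers or CRISPR
guides, screening probes for off-target sites, or annotating sequences
against a population variant catalogue. It builds an index of **every**
k-mer of an assembly (k ≤ 31), so searches are comprehensive rather than
heuristic: a k-mer that occurs exactly once is reported exactly once, with
its coordinates, and near-misses up to two mismatches are found by
construction rather than by seeding.

## The data structure

A k-mer over {A,C,G,T} packs into a 64-bit word at 2 bits/base. Keys are
scrambled by an **invertible Fibonacci hash** — multiplication by
`0x9E3779B97F4A7C15`, the odd integer nearest 2⁶⁴/φ. Because the multiplier
is odd it is a bijection mod 2⁶⁴ with a modular inverse, which enables a
quotient-filter-style **bitpacked slot layout**: a table of 2^b slots stores,
per slot, only

```
1 (occupied) + 8 (linear-probe displacement) + (64 − b) (hash remainder) bits
```

The slot's position minus its displacement gives the home bucket (the top
b bits of the hash); concatenated with the remainder this reconstructs the
full hash, and the inverse multiplier recovers the key. Keys are therefore
*never stored*, yet membership tests are exact, and lookups run in constant
expected time at bounded load factor. Values are 64-bit payloads: either one
inlined genome location (contig ordinal, offset, strand — 63 bits) or an
offset into a posting arena holding `count` followed by that many locations.

A **fuzzy query** at ≤ d mismatches enumerates the full Hamming
neighborhood of the query — `Σ 3^i · C(k,i)` codes, e.g. 2775 for k = 25 at
d ≤ 2 — and performs one O(1) lookup per neighbor, independent of genome
size.

**Variants** (SNVs and indels from a VCF) are represented as the set of
k-mers of the alternate haplotype that overlap the altered bases or span an
indel junction: k k-mers for an SNV, k − 1 for a deletion, L + k − 1 for an
insertion of L bases. Indexing these codes yields a bipartite k-mer ↔
variant graph queryable with the same machinery, carrying
coordinate/allele/type/allele-frequency metadata.

## Worked example

```r
library(fibkmer)

# a seeded 10 kb genome with 3 planted approximate repeats (truth recorded)
g <- simulate_genome(1, lengths = 10000, n_repeats = 3, repeat_k = 25, repeat_d = 1:2)
g$truth[, c("source_start", "target_start", "distance", "positions")]
#>   source_start target_start distance positions
#> 1         7295         3058        2      7,12
#> 2         2591         7700        2      7,11
#> 3         4112         3324        1         5

idx <- build_index(g, k = 25)
idx
#> <genome_index> k=25 strand=forward | 9,976 distinct k-mers, 9,976 windows, 1 contigs

# fuzzy search for the first planted repeat's source k-mer, up to 2 mismatches
fuzzy_query(idx, g$truth$source_kmer[1], 0, 2)[, c("match_kmer", "distance",
                                                   "mismatch_positions", "count")]
#>                  match_kmer distance mismatch_positions count
#> 1 CATATGCTTTATGCTTACGGCGTAC        0                        1
#> 2 CATATGTTTTAAGCTTACGGCGTAC        2               7,12     1
```

The query k-mer occurs once exactly, and its planted copy is found at
Hamming distance 2 with the mismatching bases at positions 7 and 12 — the
exact positions the simulator mutated. Per-window reports over a longer
query sequence come from `summarize_windows()` (location counts grouped by
distance: a window with `n_exact = 1, n_mm1 = 0, n_mm2 = 0` is strongly
unique) and `detail_windows()` (per-match rows with dot-notation renderings
such as `......T....A.............` and 1-based-inclusive locations like
`contig1:297-321:+`).

The same flows are scriptable from a shell via the CLI
(`inst/cli/fibkmer`): `build`, `query-seq`, `query-region`,
`build-variants`, `query-variants`, `stats` and `simulate` subcommands
write TSV summary/detail reports, truncating detail output at 1000 rows
with the remainder in an overflow sidecar file.

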
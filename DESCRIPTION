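Package: fibkmer
Title: Fuzzy K-Mer Indexing of Genome Assemblies and Variant Catalogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds queryable k-mer indices over genome assemblies using an
    invertible Fibonacci (multiplicative) hash table with linear probing and
    quotient-style bitpacked slots, so that keys are reconstructed from slot
    position rather than stored. Supports exact lookups and fuzzy queries up
    to two mismatches by Hamming-neighborhood enumeration, reporting counts,
    genomic locations and mismatch positions per query window. Also
    represents SNVs and short indels from a VCF as the set of k-mers
    overlapping the alternate allele, producing a bipartite k-mer-to-variant
    index searchable with the same machinery. Includes seeded simulators for
    genomes with planted approximate repeats and variant sets, a brute-force
    scan oracle, TSV report writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
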
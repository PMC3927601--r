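Package: islandscout
Title: Comparative Genomics of tRNA-Anchored Genomic Islands in Circular
    Bacterial Chromosomes
Version: 0.1.0
Authors@R:
    person("Islandscout", "Developers", email = "islandscout@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of finished circular bacterial
    chromosomes: in-silico restriction digestion, GC-skew profiling with
    replication origin/terminus and dif-site localisation, a seeded local
    alignment engine with Karlin-Altschul statistics, insertion-sequence
    mapping, detection of genomic islands anchored at tRNA genes by their
    3'-terminal direct repeats, three-tier gene-conservation classification,
    reconstruction of split symbiosis islands, and reciprocal-best-hit
    orthology with single-linkage protein clustering.  Includes a
    deterministic synthetic-genome generator with machine-readable truth
    ledgers so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    igraph,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: NCBI BLAST+ (optional, engine parity mode only)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
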
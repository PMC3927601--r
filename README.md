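# islandscout

Comparative genomics of finished circular bacterial chromosomes, centred on
the detection and reconstruction of horizontally acquired **genomic
islands** of the kind that carry rhizobial symbiosis genes.

Large soil bacteria such as *Bradyrhizobium* acquire nodulation and
nitrogen-fixation capability through **symbiosis islands**: hundreds of
kilobases of low-GC DNA integrated at a tRNA gene, with the intact tRNA at
one end and a short duplicated copy of its 3′ terminus at the other.  Over
time these islands fragment, leaving behind a trail of evidence — partial
tRNA relics, insertion-sequence (IS) pile-ups, and blocks of near-identical
sequence shared between strains that are otherwise ~92% diverged.
`islandscout` implements the full analytical toolkit for this kind of
comparison:

* **in-silico restriction digestion** of circular genomes
  (fragment tables as produced for PFGE cross-checks);
* **GC-skew profiling** — per-window skew S = (G−C)/(G+C), replication
  origin/terminus prediction from the extrema of the cumulative skew, and
  *dif* (dimer-resolution site) motif search with mismatches;
* a **seeded local alignment engine** (affine-gap Smith–Waterman in C++,
  exact k-mer seeding) with Karlin–Altschul statistics:
  bit = (λ·raw − ln K)/ln 2, E = m·n·2^(−bit);
* **IS mapping**: classify genome regions against a family library
  (alignments ≥ 100 bp, E ≤ 10⁻⁶⁰) and count copies per region by the
  midpoint rule;
* **tRNA-anchored island detection** by exact 3′-suffix duplication
  scanning (duplications ≥ 14 bp, nested islands up to 4 deep), plus
  duplication-free low-GC candidate islands;
* **three-tier gene conservation** against a reference genome
  (bit ≥ 100 & identity > 99% → "distinct identical"; bit ≥ 100 →
  "significant similarity"; else "no similarity"), identity histograms
  (23 × 2-point bins over 54–100%), and clustering of top-tier genes into
  loci;
* **split symbiosis-island reconstruction** from joint evidence (low GC +
  IS density + top-tier locus overlap, ≥ 2 of 3 required per fragment);
* **reciprocal-best-hit orthology** (E ≤ 10⁻⁴), three-way Venn
  partitioning by gene family, and single-linkage protein clustering
  (≥ 60% identity over ≥ 0.7 of the query);
* a **deterministic synthetic-genome generator** that plants every feature
  class above with an exact-coordinate truth ledger, so the entire
  pipeline is testable offline.

## Worked example

```r
library(islandscout)
pair <- generate_pair(synth_spec(seed = 7))
pair$genomeA
#> <annotated_genome> SYNA: 500,000 bp, circular, 73 features
#>   CDS: 64; misc: 1; tRNA: 8
```

The synthetic world is a 500-kb circular chromosome at ~63.7% GC with two
replication arcs (origin planted at 35 kb, terminus at 295 kb), a 28-bp
*dif* motif at the terminus, four genomic islands (one nested pair), ten IS
copies and a three-fragment split symbiosis island.  The detectors recover
all of it:

```r
sh <- find_skew_shifts(gc_skew_profile(pair$genomeA))
c(sh$origin, sh$terminus)
#> [1]  35000 295000

find_motif(pair$genomeA, "GGTGCGCATAATGTATATTATGTTAAAT", max_mismatches = 0)
#>    start    end strand mismatches
#> 1 295001 295028      +          0

find_trna_anchored_islands(pair$genomeA)[, c("anchor_id", "nesting_index",
    "left_end", "right_end", "length", "duplication_length", "gc_pct")]
#>   anchor_id nesting_index left_end right_end length duplication_length gc_pct
#> 1    SYNT02             1    60076     72075  12000                 46  58.83
#> 2    SYNT02             2    72076     80075   8000                 45  58.73
#> 3    SYNT03             1   200076    230075  30000                 48  59.03
#> 4    SYNT04             1   265000    269999   5000                 14  58.54
```

Each row is one island:
`SYNT02` carries two islands stacked at the same tRNA — each closed by its
own partial duplication of the tRNA's 3′ end — and every island sits well
below the genome's mean GC, the signature of foreign DNA.

Mapping the IS library and classifying genes against the diverged partner
genome, then assembling the split symbiosis island:

```r
copies <- map_is_copies(pair$genomeA, pair$is_families)
rec    <- classify_genes(NULL, pair$genomeA, pair$genomeB)
loci   <- cluster_tier1_loci(rec, pair$genomeA$features[
            pair$genomeA$features$kind == "CDS", ], pair$genomeA$length)
isl    <- find_trna_anchored_islands(pair$genomeA)
assemble_symbiosis_islands(pair$genomeA, isl, copies, loci,
                           pair$truth$symbiosis$anchor)
#> <symbiosis_island_set> anchor SYNT05: 3 fragment(s), 3 kept, total 55 kb
#>   name  start    end wraps length gc_pct is_count tier1_overlap evidence_n kept
#> 1    A 350076 390075 FALSE  40000  58.49        5          TRUE          3 TRUE
#> 2    B 150045 155044 FALSE   5000  58.88        0          TRUE          2 TRUE
#> 3    C 416274 426273 FALSE  10000  58.32        3          TRUE          3 TRUE
```

Fragment A abuts the intact tRNA-Val anchor; fragment B hangs off a 45-bp
minus-strand relic of the tRNA's 3′ end found 200 kb away; fragment C is
flagged by its IS pile-up and its overlap with a cluster of
"distinct identical" genes.  Summing the kept fragments estimates the size
of the ancestral island before it was split (here ~55 kb against a planted
54 kb).

A command-line surface wraps the same operations
(`inst/cli/islandscout convert|digest|skew|islands|ismap|conserve|symbiosis|orthovenn|simulate|report`).

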
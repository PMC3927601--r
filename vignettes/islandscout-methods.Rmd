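---
title: "Models and methods behind islandscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind islandscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`islandscout` analyses finished circular bacterial chromosomes for the
fingerprints of horizontal DNA acquisition: genomic islands integrated at
tRNA genes, insertion-sequence (IS) expansions, replication-strand
asymmetry, and blocks of anomalously conserved sequence between diverged
strains.  This vignette records the models, the tunable parameters with
their defaults and the reasoning behind them, what the synthetic test
world does and does not emulate, and the numerical conventions.

## Coordinates and the circular data model

All external coordinates are 1-based and inclusive.  A replicon is a
single circular (or linear) sequence plus a typed feature table; intervals
that cross the origin carry a `wraps` flag and render in the
`start-0-end` style used in genome tables for origin-spanning loci.  The
length of a wrapped interval is `L - start + 1 + end`.  GC content is
`100·(G+C)/(A+C+G+T)`: `N` bases count toward interval length but are
excluded from both numerator and denominator, so gapless finished genomes
and gappy synthetic ones are treated consistently.

## In-silico digestion

Restriction sites are found by scanning the top strand of the circle
(including motif occurrences spanning the origin, and counting overlapping
occurrences at every start).  Only palindromic enzymes are supported —
for a palindrome the top-strand scan is exhaustive — and non-palindromes
are rejected explicitly rather than silently half-searched.  The built-in
definitions are the standard ones: PmeI `GTTTAAAC` cut after 4, SwaI
`ATTTAAAT` cut after 4, PacI `TTAATTAA` cut after 5.  A circular genome
with *k* pooled cut positions yields exactly *k* fragments summing to the
genome length (one full-length fragment when *k* = 0); linear input yields
*k* + 1.  Kilobase columns round half away from zero, matching the usual
presentation of digest tables.

## Replication skew and dif

Per-window GC skew is (G−C)/(G+C) (0 where G+C = 0) over windows that
wrap the circle; the default window is 10 kb with step = window/10, the
conventional resolution for Mb-scale chromosomes.  Origin and terminus
candidates come from the extrema of the *cumulative* per-chunk (G−C)
track rather than sign changes of the windowed values: cumulative extrema
are robust to local noise, and the chunks are disjoint so the final
cumulative value equals the genome's total G−C (a checked invariant).
Ties break to the smallest coordinate; a perfectly flat profile returns
an explicit "no shift detected" result instead of an arbitrary position.

The *dif* dimer-resolution site is searched as a user-supplied 28-mer
consensus with a Hamming tolerance (default 4 mismatches), on both
strands, wrapping allowed, ranked by distance then coordinate.  The
consensus is configuration, not hard-coded biology: the default is the
*E. coli* dif sequence, and analyses of other clades should supply their
own.  Because the consensus and tolerance are configurable, dif
coordinates are a config-dependent observation, not a guaranteed output.

## The alignment engine

Local alignment uses affine-gap Smith–Waterman (Gotoh) implemented in
C++, with a gap of length *k* costing `gap_open + k·gap_extend`.
Nucleotide defaults are match +2 / mismatch −3, gap 5/2, with published
Karlin–Altschul constants for that scheme (λ = 0.625, K = 0.41); protein
mode uses BLOSUM62 with gap 11/1 (λ = 0.267, K = 0.041).  Bit score and
E-value follow the standard definitions with search space m·n and no edge
correction — deviations are absorbed by the configurable cutoffs.

Small problems (≤ ~4·10⁶ cells) run the exact dynamic program over the
full matrix, so the engine is *provably* optimal at the scale where the
test oracle (an independent DP implementation) checks it.  Large subjects
use exact k-mer seeding: query k-mers are looked up in a sorted code
index of the subject, seeds are grouped into diagonal-band clusters, and
each cluster is refined by running the full DP inside a bounded subject
window.  Two design choices matter here:

* **Seed length 13** (not the more conventional 11): against multi-Mb
  subjects an 11-mer produces ~`L·m/4¹¹` chance seeds, dense enough that
  diagonal clusters coalesce and the "bounded" windows degenerate toward
  the whole genome.  At k = 13 chance seeding is ~16× sparser while
  targets at ≥ 90% identity — the regime every analysis here operates
  in — still seed each true diagonal hundreds of times.  Seed codes stay
  within 32-bit integers.
* **Window refinement instead of X-drop extension**: rather than greedy
  extension with a drop-off parameter, each seed cluster is re-aligned
  exactly within a window ~3 query lengths wide.  This is simpler, exact
  within the window, and its cost is bounded by the cluster count.
  Isolated single-seed diagonals (almost always chance matches) are
  ignored unless nothing better exists.

Overlapping hits on the same strand (> 50% subject overlap) collapse to
the best-scoring.  Best-hit ranking is bit score (desc), then E-value
(asc), then database order and coordinate — a deterministic tie rule.
An optional parity adapter runs an installed BLAST+ on the same FASTA
inputs and parses its tabular output, used only to cross-validate the
internal engine; it is never a dependency.

Score thresholds quoted as plain "score ≥ 100" in the conservation
analysis are interpreted as **bit** scores; thresholds of that magnitude
conventionally refer to bit scores in BLAST reports.  Both
interpretations remain available because the threshold is a parameter.

## IS atlas

IS copies are genome regions aligning to a family reference with
aligned length ≥ 100 bp and E ≤ 10⁻⁶⁰ — thresholds appropriate for long,
recently mobile, near-identical repeats against a Mb-scale genome.
Overlapping assignments resolve to the best bit score, and same-family
hits overlapping by more than half merge into one copy (this prevents
seeded sub-alignments of one element being double-counted; how partial
and nested hits merge into "copies" is genuinely under-determined in this
kind of analysis, so the rule is explicit and configurable).  Region
tallies use the copy midpoint — deterministic for boundary-straddling
copies — with copies outside every named region counted as "backbone",
and loosening the E-value cutoff can only add copies (a tested
monotonicity).

## tRNA-anchored islands

The island model: an integrative element recombines into a tRNA gene so
that the intact gene flanks one end and a short duplicate of the gene's
3′-terminal bases flanks the other.  Detection therefore scans strictly
downstream of each tRNA's 3′ end *on the tRNA's coding strand*, looking
for exact occurrences of gene suffixes of at least `min_dup` = 14 bp (the
smallest duplication observed in finished genomes of this kind; the
intended threshold in the field is not standardised, so it is a
parameter).  At each occurrence the longest matching suffix is taken.
Matching is exact string equality: at 14–53 bp, observed duplications are
effectively exact, and exactness keeps precision clean; a
mismatch-tolerant mode would live behind configuration if needed.

Each successive duplication closes one island — nested islands at
integration hotspots tile the interval from the tRNA 3′ end outward with
no gaps — up to `max_stack` = 4 islands per anchor (the deepest stacking
reported at such hotspots) and `max_island` = 110 kb per island (just
above the largest single island on record in this genus).  Islands whose
GC is not below the genome mean are dropped by default: every credible
island in this clade is GC-depressed, and the filter is switchable for
exploration.  A putative integrase is attached when a CDS annotated with
integrase/recombinase keywords lies inside the island.

**Candidate islands** handle the case where the terminal duplication has
eroded: maximal runs of low-GC windows downstream of a tRNA that has *no*
duplication-delimited island, of at least 10 kb.  "Low" means below the
genome mean minus `gc_margin` = 2 points, measured in 5-kb windows.
These two defaults are set by noise arithmetic: a 5-kb window of ~64% GC
background has a GC standard deviation of ~0.7 points, so a 2-point
margin sits ~3σ clear of background while remaining ~3σ above planted
island GC (~59%); a 1-point margin at 1-kb windows — the naive choice —
is *inside* the background noise band and produces runaway growth.  The
trade-off: genuinely mild GC anomalies (within ~1 point of the mean) will
not be nominated at the defaults.

**Partial tRNA relics** are found by exact genome-wide search (both
strands) for the 3′-terminal `min_len` = 45 bp of a tRNA, extended to the
longest matching suffix; hits extending to the full gene length (the
intact gene and identical full copies) are excluded.  Minus-strand relics
report descending coordinates, the convention used for such fragments.

## Split symbiosis-island reconstruction

An ancestral island that was split by large-scale rearrangement leaves
three recognisable fragments: **A**, the low-GC region still abutting the
intact anchor tRNA (tRNA-Val in the motivating system); **B**, a low-GC
region adjacent to a distal partial copy of the anchor's 3′ terminus,
typically with a neighbouring integrase; and **C**, a region flagged
jointly by IS density and overlap with a cluster of near-identical
("tier 1") genes.  Fragments are grown window-wise from their seed points
(the anchor 3′ end, the partial copy, the densest free IS cluster) using
the same low-GC growth as candidate islands, so boundary error is bounded
by one window.  Each fragment must satisfy at least two of {low GC, IS
density ≥ 5 copies/100 kb, tier-1 locus overlap}; fragments failing that
are retained in the output with their evidence vector but flagged
`kept = FALSE`, and a result with fewer than three kept fragments is
explicitly `complete = FALSE` rather than an error.  The IS-density
threshold is a rule this package had to choose (the motivating analyses
report counts, not a rule); 5/100 kb is an order of magnitude above
backbone density in the systems of interest.

## Conservation tiers, histogram, loci

Every query gene's nucleotide sequence is searched against the full
partner genome (both strands).  Tiers: bit ≥ 100 and identity strictly
greater than 99% → `distinct_identical`; bit ≥ 100 otherwise →
`significant_similarity`; else `no_similarity`.  "Over 99%" is read
strictly, and the partition is exhaustive and mutually exclusive.

The identity histogram uses 23 equal-width bins over 54–100% — 2-point
bins are the only equal-width layout consistent with 23 groups across the
observed identity range — with the top bin right-closed and out-of-range
identities clamped (with a warning).  The binned population is switchable
between "all qualifying genes" (tiers 1+2, the default, matching how such
histograms total both tiers) and the middle tier only, because published
figures are ambiguous between the two accountings.

Tier-1 loci are runs of `distinct_identical` genes with inter-gene gaps
≤ 25 kb (strain-specific islets larger than 10 kb interrupt real loci, so
the gap tolerance must exceed 10 kb with headroom), at least 3 genes per
locus, wrapped loci supported by stitching the first and last runs across
the seam.

## Orthology

Reciprocal best hits use protein mode with E ≤ 10⁻⁴.  The three-way Venn
links the three pairwise RBH graphs into connected components and counts
**families** (components) per region by default — a non-redundant union
accounting, matching how three-way proteome totals are de-duplicated — with
a per-gene accounting available.  Single-linkage clustering links pairs at
≥ 60% amino-acid identity with the alignment covering ≥ 0.7 of the query
length; coverage is tested in both orientations and either passing
suffices, which makes the criterion symmetric as a clustering relation
demands.  The transitive closure is computed with igraph; the test suite
re-derives it with an independent hand-written union-find over an
independently computed pair list.

## The synthetic world

`generate_pair()` emits the stated world everything is tested against.
Defaults, chosen once:

| parameter | default | why |
|---|---|---|
| genome length | 500 kb | ~18× scaled-down from a 9.2-Mb chromosome; large enough for Mb-scale machinery (seeding, windows), small enough for minutes-scale tests |
| background GC | 63.67% | the GC of the motivating genome |
| skew arcs | boundaries at 0.07·L and 0.59·L, bias ±0.03 | origin/terminus fractions of the motivating chromosome; bias gives skew amplitude ~0.09, a realistic signal |
| background divergence | 0.08/site | yields ~92% gene identity, the modal conservation band between diverged conspecific strains |
| island / fragment GC | 59% | the level observed for real islands |
| symbiosis fragments | 40 kb / 4 kb / 10 kb | fragment B kept at its literal 4 kb (it is a 4-kb region in the motivating system); A and C scaled with the genome |
| symbiosis divergence | 0.002/site | keeps fragment genes above the 99% tier-1 line with wide margin (a 300-bp gene crosses 99% only with ≥ 4 substitutions, P ≈ 0.003) |
| duplications | 14–53 bp | the observed range |

Generator mechanics worth knowing:

* **Determinism**: one seeded RNG stream drives everything; identical
  spec + seed reproduce byte-identical FASTA.
* **Guarded low-GC content**: island/fragment sequence is drawn in 1-kb
  chunks, redrawn until each chunk's GC lies within 1.2 points of target
  (and below the detection guard).  Real islands have heterogeneous GC;
  the generator deliberately emulates *uniformly* depressed GC so that
  window-growth boundary recovery is well-defined and the realized
  region GC lands within a point of plan.
* **Spurious-match sweeps**: after planting, accidental occurrences of
  any tRNA's 14-bp 3′ suffix outside planted loci are mutated away, so
  island precision 1.0 is a property of the detector, not luck.  The
  partner genome's substitutions are likewise reverted wherever they
  would create a restriction site or tRNA-suffix match absent from the
  source genome.
* **CDS termini are conserved**: the partner genome never substitutes
  the first/last 6 bp of an annotated CDS.  Start/stop codons do not
  drift between conspecific strains, and this anchors local alignments
  end-to-end so per-gene alignment identities are directly comparable
  with the ledger's whole-gene substitution tallies.
* **Proteome triples**: `generate_triple()` emits three protein sets
  (plus truth), not full chromosomes — the Venn and clustering analyses
  consume proteomes, and DNA context would add nothing the tests could
  check.

What the synthetic world does **not** emulate: indels and rearrangements
(divergence is substitution-only), codon structure and realistic tRNA
secondary structure, IS terminal inverted repeats and target-site
duplications, GC heterogeneity inside islands, and features spanning the
replication origin.  A green test therefore establishes that the
detectors are *correct against their models* — exact duplication
recovery, oracle-equal alignment scores, truth-equal counts — not that
the models capture every messiness of real genomes; runs on deposited
genomes remain the validation for that.

## Numerical conventions and degenerate inputs

Rounding is half-away-from-zero for kb tables and 2 decimals for
percentages.  All extremum and best-hit ties break toward the smallest
coordinate / earliest database entry.  Flat skew profiles, empty motif
hits, genomes without tRNAs, missing anchors, sub-100-bp IS references,
non-palindromic enzymes and infeasible synthetic packings all fail (or
return empty) explicitly, with messages naming the offending object.
E-values use the full m·n search space; no composition-based score
adjustment or gapped-statistics refinement is applied.

## Known limitations

* The seeded aligner can miss homology below ~85% identity when the
  subject is large (no 13-mer seed survives); at the identity regimes of
  these analyses (≥ 90%) this is immaterial, and small inputs always get
  the exact DP.
* Alignments never wrap the origin; rotate the genome first if a feature
  of interest spans it.
* Island duplication matching is exact; heavily eroded duplications
  surface only through the low-GC candidate route.
* Fragment-B orientation logic assumes the partial relic retains its
  strand sense; a relic inverted *in situ* after fragmentation would
  grow the fragment on the wrong side.
* The GenBank reader covers the single-record bacterial flat files this
  package writes and the common location forms (`complement`, two-part
  origin-wrapping `join`); exotic locations (multi-part joins,
  `order()`, remote accessions) are rejected with a parse error.
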
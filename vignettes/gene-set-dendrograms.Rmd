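---
title: "Relating diseases and phenotypes by gene sharing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating diseases and phenotypes by gene sharing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhenoShare)
```

## The model

PhenoShare treats a disease or phenotype term as nothing more than the
set of genes attached to it, and derives all structure from set overlap.
That is a deliberately minimal model. Its assumptions are worth stating
plainly:

* **A record is evidence, not proof.** Association records carry a Y/N
  flag per publication; only positively flagged, annotated records enter
  the analysis, and the per-pair co-occurrence count (how many records
  pair gene *g* with term *t*) is retained as a crude replication
  weight in the summaries, though set membership itself is binary.
* **Gene symbols identify genes.** Human symbols are uppercased on
  ingestion; mouse symbols are kept as-is, and the two namespaces are
  only ever joined through an explicit ortholog table (a case-matching
  fallback exists but is off by default, because symbol coincidence
  across species is error-prone).
* **Sharing is relative to the smaller set.** The distance
  `1 - |intersection| / min(sizes)` scores a rare syndrome nested in a
  broad disease as identical (distance 0). The resulting dissimilarity
  is *not* a metric — subset chains break the triangle inequality — and
  none of the downstream methods (Neighbor-Joining, least-squares
  fitting, Ward on membership vectors) require it to be one.

## Trees

`njTree()` is the standard Saitou–Nei agglomeration. Two contracts are
stronger than the textbook algorithm and deserve explanation:

* **Determinism.** Ties in the Q criterion are resolved by joining the
  lexicographically smallest label pair. Gene-set matrices genuinely
  produce ties (duplicate sets at distance 0, many exactly-disjoint
  pairs at distance 1), and a reproducible tree is worth the arbitrary
  rule. This is also what makes `randomizedReplicates()` informative:
  permuting the input order re-rolls only the genuinely tied decisions,
  so topology that survives 25 permutations is not an input-order
  artifact. `groupIsSplit()` and `rfDistance()` quantify that stability.
* **Negative branch lengths are kept.** They are legal NJ output on
  non-additive input; clamping them (available via `clampNegative`)
  silently changes path distances and hence the Fitch–Margoliash score,
  so it is opt-in.

`fmCriterion()` evaluates Σ n(D−d)²/D^P with P = 2
(Fitch–Margoliash) or P = 0 (unweighted); `fitBranchLengthsLS()`
minimizes the same quantity over branch lengths on a fixed topology,
which is a weighted linear least-squares problem on the path-incidence
system. A full Fitch–Margoliash *topology* search is intentionally not
provided: at gene-set scale it is combinatorially hopeless, and
criterion-scoring NJ-proposed (or user-supplied) topologies preserves
the scoring semantics at desk scale. Two numerical choices matter:

* **Zero observed distances.** Duplicate or nested gene sets give
  D = 0, and the criterion divides by D^P. The denominator is floored
  at `denomEpsilon` (default 1e-6, configurable in `fmConfig()`).
* **Replicate weights.** n defaults to 1 for every pair, the simple
  case; a vector can be supplied when distances are averages of
  replicated measurements.

## Ward clustering

`wardCluster()` clusters gene sets as binary membership vectors over
the sorted gene universe, unweighted by co-occurrence counts (a
count-weighted variant is reachable via `binary = FALSE`). The merge
height is the increase in within-cluster sum of squares,
`‖x̄_K − x̄_L‖² / (1/N_K + 1/N_L)`; the implementation uses the
Lance–Williams recurrence seeded with half the squared Euclidean
distances, which is algebraically identical to recomputing centroid
distances each step and is verified in the test suite against a
brute-force implementation that recomputes within-cluster sums of
squares from the definition for every candidate merge (n ≤ 7), and
against `stats::hclust(method = "ward.D")` on tie-free continuous data.
Equal merge heights are resolved by the smallest (min index, max index)
pair; with binary data ties are common, and two correct Ward
implementations with different tie rules can legitimately diverge after
a tie, which is why the oracle comparison pins the tie rule. The number
of clusters `k` in `cutDendrogram()` is a user decision; the package
deliberately ships no automatic cut criterion.

## The synthetic generator

`simulateGadRecords()` emulates the *structure* of an
association-record dump: K disease groups own disjoint core gene pools,
each term draws its group's core genes with probability `pIn` (default
0.6) and every other gene with probability `pBg` (0.02), each planted
(gene, term) pair is replicated r times with r from a truncated Zipf
law (exponent 1.5, max 70 — matching the heavy-tailed replication
pattern of curated association counts, where top genes are reported
dozens of times and most exactly once), and noise records are appended
so the table's gross composition matches a real dump's (~26% positively
flagged and annotated, ~29% flagged at all, a few percent missing
annotations). The planted stratum is exactly the Y + annotated records:
flag noise is added *around* the signal rather than thinning it, which
keeps the ground truth exact and gives `filterRecords()` real work. The
default sizes (5 groups × 8 terms, 30-gene cores in a 300-gene
universe) keep every test and the acceptance script in seconds while
leaving enough overlap noise that recovery is not trivial.

What the generator does **not** emulate: correlated publication bias,
MeSH term hierarchy (terms are exchangeable labels), partial overlap
*between* group cores, and realistic gene-frequency skew across terms.
Passing the planted-recovery tests therefore shows the pipeline is
correct and well-conditioned at realistic sharing rates — not that real
GAD/MGI snapshots would cluster as cleanly; snapshot-level counts are
out of scope throughout.

`simulateMgiFiles()` produces a parseable OBO ontology (root, one class
term per group, one leaf per phenotype) and a gene–phenotype report
with the same planted logic under mouse-cased symbols;
`simulateOrthologMap()` links the two species at a configurable
coverage. Every generator restores the caller's RNG state, so seeds are
strictly local.

## File formats

GMT, square PHYLIP, Newick and the tab-delimited tables round-trip
losslessly (property-tested). Disease labels exceed PHYLIP's 10-character
field, so `writePhylipMatrix()` always emits stable 10-character tokens
plus a sidecar name map. Newick labels containing metacharacters
(spaces, commas, parentheses — routine in MeSH terms) are single-quoted
on writing and unquoted on reading; branch lengths are written at a
fixed 6 decimals so replicate outputs are byte-comparable.

## Problem sizes and verification

The shipped validation uses: 200 random additive matrices (5–12 leaves)
for NJ consistency; 50 noisy instances against an independent
normal-equations branch-length oracle (tolerance 1e-8); 100 random
binary matrices (n ≤ 7) against the brute-force Ward oracle; 1,000
random record tables for summary duality/conservation; 20 generator
seeds for planted-group recovery (adjusted Rand index at k = 5) plus 25
randomized-order NJ replicates for same-group monophyly; and the
11-term cardiovascular fixture, where the Hypertension and Myocardial
Infarction top-8 lists share {ACE, NOS3} and must score exactly 0.75.
`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed.

## Known limitations

* Analyses are at the gene level only; variant-level genetics, effect
  sizes and directions of association are not modeled.
* Pathway projection (`projectToAnnotations()`) uses a shared-gene
  threshold, not an enrichment statistic; it answers "do these
  disorders touch the same pathways", not "is that overlap surprising".
* The cross-species table juxtaposes human and mouse term lists; it
  does not attempt semantic matching between MeSH and MP vocabularies.
* Cluster-count selection and dendrogram rendering are out of scope.
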
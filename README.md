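# PhenoShare

Gene-sharing analysis of disease and phenotype gene sets.

Common human diseases are polygenic and their genes pleiotropic: the same
gene turns up in association studies of many disorders, and mouse mutants
of its ortholog show many phenotypes. PhenoShare turns that sharing into
quantitative structure. It is aimed at researchers holding GAD-style
association record tables (gene × MeSH disease term × publication with a
Y/N flag) and/or MGI-style mouse phenotype annotations (gene × Mammalian
Phenotype code), who want to ask which disorders are genetically related,
whether related disorders share more pathways than genes, and whether
human association evidence is mirrored by mouse mutant phenotypes.

## The method

1. **Gene sets.** Records are filtered to positively associated (`Y`),
   MeSH-annotated rows; gene–term co-occurrences are counted and every
   disease (or phenotype) term with enough genes becomes a gene set
   *C*<sub>k</sub> with *N*(*C*<sub>k</sub>) unique members.
2. **Overlap-coefficient distance.** For sets *i*, *j*:

   *d*<sub>ij</sub> = 1 − |*C*<sub>i</sub> ∩ *C*<sub>j</sub>| / min(*N*(*C*<sub>i</sub>), *N*(*C*<sub>j</sub>))

   so identical or nested sets are at distance 0 and disjoint sets at 1.
   Deliberately not a metric — a small syndrome fully contained in a
   broad disease counts as a perfect match.
3. **Dendrograms.** Neighbor-Joining on the distance matrix, with
   randomized-input-order replicates, tree comparison by Robinson–Foulds
   distance, and tree scoring under the Fitch–Margoliash weighted
   least-squares criterion

   Σ<sub>i&lt;j</sub> *n* (*D*<sub>ij</sub> − *d*<sub>ij</sub>)² / *D*<sub>ij</sub><sup>*P*</sup>

   with *P* = 2 (Fitch–Margoliash) or *P* = 0 (unweighted); branch
   lengths on any fixed topology are refit by weighted linear least
   squares on the path-incidence system.
4. **Ward clustering.** Gene sets become binary membership vectors over
   the gene universe; agglomerative merging minimizes the increase in
   within-cluster sum of squares,
   *D*<sub>KL</sub> = ‖x̄<sub>K</sub> − x̄<sub>L</sub>‖² / (1/*N*<sub>K</sub> + 1/*N*<sub>L</sub>).
5. **Cross-species tables.** Human by-gene summaries are joined to mouse
   by-gene summaries through an explicit ortholog map, one row per
   shared gene, listing both species' terms side by side.

A synthetic-data generator plants known disease-group structure
(group-specific core gene pools, configurable sharing and noise rates)
so the whole pipeline is testable end to end with known ground truth.

## Worked example

The package ships the published top-8 gene lists for 11 cardiovascular
MeSH terms (`inst/extdata/gad_cardiovascular_top8.tsv`), e.g.
Hypertension: ACE(47), AGT(24), NOS3(20), … and Myocardial Infarction:
NOS3(18), ACE(17), SERPINE1(11), …

```r
library(PhenoShare)
s <- readSummaryTable(system.file("extdata", "gad_cardiovascular_top8.tsv",
                                  package = "PhenoShare"), axis = "by_term")
gsc <- buildGeneSets(s, minSize = 3)

overlapDistance(gsc[["Hypertension"]], gsc[["Myocardial Infarction"]])
#> [1] 0.75
```

The two 8-gene lists share {ACE, NOS3}, hence 1 − 2/8 = 0.75.

```r
tr <- njTree(setDistanceMatrix(gsc))
cat(writeNewick(tr))
#> (Arteriosclerosis:0.277344,('Cardiovascular Diseases':0.182292,
#>  'Coronary Artery Disease':0.192708):0.035156,(((Cardiomyopathies:0.520833,
#>  'Venous Thrombosis':0.479167):0.115625,...);

cl <- cutDendrogram(wardCluster(membershipMatrix(gsc)), 3)
split(names(cl), cl)
#> $`1`
#> [1] "Arteriosclerosis"        "Cardiovascular Diseases"
#> [3] "Coronary Artery Disease" "Coronary Disease"        "Myocardial Infarction"
#> $`2`
#> [1] "Cardiomyopathies"  "Venous Thrombosis"
#> $`3`
#> [1] "Heart Failure"  "Hypertension"  "Hypertrophy, Left Ventricular"
#> [4] "Myocardial Ischemia"
```

Coronary/atherosclerotic disorders, clotting-related disorders and
pressure/pump disorders separate purely by gene sharing — no disease
labels or ontology enter the computation.

A shell front end wraps the same functions
(`simulate`, `summarize`, `genesets`, `venn`, `distance`, `tree`,
`cluster`, `crossmap`):

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "phenoshare", package = "PhenoShare"))')
Rscript "$CLI" simulate --seed 7 --out-dir sim/
Rscript "$CLI" summarize --records sim/records.tsv --axis by_term --out sim/byterm.tsv
Rscript "$CLI" genesets --summary sim/byterm.tsv --min-size 3 --gmt-out sim/sets.gmt
Rscript "$CLI" tree --matrix sim/D.phy --reps 25 --seed 17 --newick-out sim/trees/
```

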
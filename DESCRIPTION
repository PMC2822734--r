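Package: PhenoShare
Title: Gene-Sharing Analysis of Disease and Phenotype Gene Sets
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds disease and phenotype gene sets from genetic-association
    records (human, GAD-style) and mutant-phenotype annotations (mouse,
    MGI/Mammalian Phenotype style), quantifies gene sharing between sets with
    the overlap-coefficient distance (one minus the shared-gene count divided
    by the smaller set size), and relates sets by Neighbor-Joining dendrograms
    scored under the Fitch-Margoliash weighted least-squares criterion and by
    Ward minimum-variance hierarchical clustering of binary membership
    vectors. Includes readers and writers for tab-delimited association
    tables, OBO ontology subsets, GMT gene-set collections, square PHYLIP
    distance matrices with sidecar name maps, Newick trees and two-column
    ortholog maps; cross-species human-mouse shared-gene tables; and a
    synthetic-data generator with planted disease-group structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Clustering, GraphAndNetwork, Phylogenetics, GeneSetEnrichment
RoxygenNote: 7.3.3
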
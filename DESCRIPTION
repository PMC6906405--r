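Package: netseed
Title: Protein Interaction Network Guided Exome Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Targeted case-control exome association analysis guided by a
    protein-protein interaction (PPI) network. Expands a curated seed gene
    set to its first neighbours in a background interactome, filters exome
    variants to the expanded gene set plus flanking windows, runs
    single-variant logistic association with principal-component ancestry
    covariates and genomic-inflation QC, selects candidate variants by a
    p-value threshold scan, builds a log odds-ratio weighted polygenic
    risk score with replication testing, evaluates variant and PRS
    disease-prediction models, and assesses subnetwork topology (average
    path length, clustering) against a degree-binned label-permutation
    null with Monte Carlo p-values. A synthetic-data module simulates
    interactomes, gene maps and stratified case-control genotype panels
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    pROC,
    randomForest,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
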
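Package: uroclust
Title: Molecular Subtype Discovery and Cross-Omics Transfer for Urothelial Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-cluster molecular classification framework for bulk
    urothelial-carcinoma transcriptomes and proteomes: self-organising-map
    metagenes, single-sample gene-set enrichment (ssGSEA) scoring,
    hard-threshold regularised k-means with feature selection, and transfer of
    cluster labels to new cohorts, proteomes and cell lines by inverse
    distance-weighted k-nearest-neighbour and multinomial elastic-net
    classifiers. Downstream characterisation tools include a composite
    differential-regulation caller with DerSimonian-Laird random-effects
    meta-analysis, cohort-stratified permutation tests of mutation enrichment,
    Spearman and Jaccard networks with Leiden communities, Monte-Carlo
    gene-protein-reaction metabolic activity modelling, bootstrap analysis of
    CRISPR knockout effects, ridge drug-response prediction, and the clinical
    effect-size and survival statistics used to characterise the clusters.
    A multi-cohort synthetic-data generator emulates the statistical structure
    of the real studies so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    igraph,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    mclust,
    MASS
Config/testthat/edition: 3
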
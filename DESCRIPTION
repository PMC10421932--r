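Package: ly6tools
Title: Exon-Aware Reconstruction and Classification of LY6/Three-Finger-Toxin Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the evolution of the LY6/UPAR (three-finger
    fold) gene family: a synthetic-genome generator that emulates the
    marker-anchored LY6/3FTX cluster with pseudogenes, orphan exons and
    duplicated exon-3 genes; a translated Smith-Waterman exon-homology search
    with dynamic-programming chaining into gene models and synteny maps;
    cysteine-framework extraction and four-category classification of mature
    three-finger proteins with membrane-anchoring-tail detection; feature-space
    construction, UMAP projection, k-means/DBSCAN/OPTICS clustering and
    partition concordance; and desk-scale neighbor-joining tree building with
    Robinson-Foulds comparison and monophyly testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    uwot,
    mclust,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
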
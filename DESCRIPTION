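Package: posclust
Title: Positional Clustering of Co-Expressed Genes Along Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies positional clusters of genes - runs of two or more
    genes on the same chromosome whose consecutive start coordinates lie
    within a base-pair distance threshold - after optional selection of genes
    by expression level. Provides readers and writers for the whitespace
    delimited gene data (GDF) and cluster (CLU) text formats, merging of
    Biomart-style position tables with multi-condition expression tables,
    expression-threshold filtering, iterative cluster updating with new gene
    sets, a random-gene-set baseline with a one-sample t-test for cluster
    significance, cluster-size statistics, scalable vector graphics views of
    clusters along chromosomes and of single-cluster expression profiles, a
    deterministic synthetic-data generator with planted clusters, and a
    scriptable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
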
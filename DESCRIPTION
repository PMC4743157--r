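Package: termclouds
Title: Word-Cloud Summary Figures for Gene-List Enrichment and Ordination Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional characterisation of many gene lists at once. Provides a
    local hypergeometric over-representation engine against GMT gene-set
    annotations, a three-stage term filtering pipeline (size window,
    parent-sharing redundancy reduction on the ontology DAG, top-N cap), a
    deterministic word-cloud layout engine in which font size encodes
    -log10(p) and a figure-wide grayscale encodes absolute enrichment
    strength, and producers that turn k-means cluster assignments,
    differential-expression tables, PCA loadings and PCoA axes (Bray-Curtis,
    Spearman feature association) into stacked summary figures combining word
    clouds with panels of the underlying data. Includes seeded synthetic-data
    generators so the whole pipeline is testable offline, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    igraph,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
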
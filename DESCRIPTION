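Package: rhizonet
Title: Fungal-Bacterial Co-Occurrence Network Analysis for Plant Rhizobiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Workflow for analysing joint fungal-bacterial OTU count tables
    from trap-plant rhizobiome experiments: Hellinger normalisation,
    rank-abundance and rarefaction summaries, sample-similarity maximum
    spanning trees (Pearson and proportional similarity), OTU-sample and
    genotype-binned enrichment hypergraphs (Fisher exact test with FDR
    control) with a genotype-specificity quotient, OTU co-occurrence
    networks clustered into communities with the Markov Cluster algorithm,
    soil-property correlation mapping onto communities, fold-change
    rank-order (FCROS) differential abundance, indicator-species analysis
    with site-group combinations, PERMANOVA/PERMDISP, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
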
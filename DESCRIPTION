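Package: hadalCLPP
Title: Community-Level Physiological Profiling and Co-Occurrence Networks
    for Deep-Sea Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing microbial community metabolic activity and
    co-occurrence structure in stratified marine water columns. Implements
    turbidity-corrected Biolog EcoPlate kinetics (average well colour
    development, substrate richness, Simpson and Shannon functional-diversity
    indices, per-category carbon utilisation, growth-phase detection),
    ASV-table community statistics (relative abundance, Shannon/evenness,
    Bray-Curtis dissimilarity, permutation ANOSIM), and co-occurrence network
    inference (top-abundance ASV selection, Spearman correlation with
    Benjamini-Hochberg FDR edge filtering, Louvain modularity, taxonomy-aware
    signed-edge summaries). A synthetic-data module generates plate time
    series with logistic colour development and ASV tables with planted
    correlated guilds so the whole pipeline is testable without raw data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
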
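Package: rmnet
Title: Rule-Based Microbial Interaction Networks from Relative Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Infers directed, signed ecological interaction networks among
    microbial taxa or oligotypes from multi-sample relative-abundance tables
    using a rule-based triplet model: every ordered (target, cooperator,
    competitor) triplet is scored against discretized abundance changes across
    sample pairs, and conforming triplets are assembled into a network of
    cooperative and competitive edges.  Also provides entropy-based
    oligotyping of aligned amplicon reads, mothur-compatible alpha-diversity
    estimators (observed richness, Good's coverage, Chao1, plug-in and
    coverage-adjusted Shannon, unbiased inverse Simpson, evenness) with
    rarefaction, readers and writers for the mothur 'relabund'/'shared' and
    oligotyping 'matrix_percents' tabular dialects, GraphML/DOT/edge-list
    export, a synthetic-community generator with planted interactions for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Biostrings,
    optparse,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
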
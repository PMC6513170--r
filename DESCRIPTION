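Package: gevit
Title: Systematic Construction of a Visualization Design Space from a
    Literature Corpus
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for systematically surveying the data visualizations of a
    research community. A literature-analysis pipeline turns titles and
    abstracts into a stemmed tf-idf document-term matrix, embeds it with
    Barnes-Hut t-SNE, derives topic clusters through an HDBSCAN
    minimum-cluster-size stability sweep, validates clusters against an
    external controlled vocabulary, links documents to a priori concepts via
    curated bigram mappings, and performs stratified document sampling with
    rejection and resampling bookkeeping. A machine-readable visualization
    typology (chart types, chart combinations, chart enhancements) supports
    annotation validation, rule-based combination and enhancement
    classification, design-space frequency analytics and static gallery
    export. Synthetic-data generators with planted ground truth make every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    Rtsne,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
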
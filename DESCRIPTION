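Package: gsmtopics
Title: Topic-Based Feature Selection for Short-Text Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grouping-Scoring-Modeling (G-S-M) feature selection for binary
    classification of short texts such as article titles. Words are grouped
    into topics by a native Dirichlet-multinomial mixture topic model fitted
    with collapsed Gibbs sampling (GSDMM); each topic is scored by internal
    cross-validation of a random-forest classifier on its term slice of the
    bag-of-words table; top-ranked topics are accumulated and, optionally,
    fused with the document-topic distribution to train the final classifier
    under stratified Monte-Carlo cross-validation. Includes a Snowball
    (Porter2) preprocessing pipeline, importers for externally trained
    topic-model artifacts, a synthetic short-text corpus generator with
    class-linked topics, and writers for all intermediate artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
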
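Package: cooctopics
Title: Topic Detection in Short Texts via PMI Co-Occurrence Networks and Louvain Modularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting discussion topics in short social-media
    texts (tweets) about palliative and end-of-life care during the COVID-19
    pandemic. Provides keyword filtering of a tweet stream against a curated
    search filter, gazetteer-based resolution of free-text profile locations to
    countries, temporal partitioning around per-country vaccination start
    dates, a four-step text preprocessing chain (cleaning, tokenization,
    stopword removal, lemmatization), construction of term co-occurrence
    networks weighted by pointwise mutual information, community detection via
    an original implementation of Newman modularity and the two-phase Louvain
    algorithm, and topic reporting with ranked keywords, representative
    documents and pre/post-period comparison. A synthetic corpus generator with
    planted topics supports end-to-end evaluation without access to platform
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
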
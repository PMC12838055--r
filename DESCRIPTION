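Package: semanchor
Title: Anchor-Based Semantic Scoring and Psychometric Network Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores open-response descriptor terms against a facet anchor
    lexicon in a shared embedding space, aggregates term-facet cosine
    similarities into standardized person-by-facet composites, and runs the
    psychometric evaluation battery used for expressive-semantic instruments:
    McDonald's omega and hierarchical omega via a Schmid-Leiman decomposition
    with percentile bootstrap intervals, intraclass correlations for rater
    agreement, EBIC-selected graphical-lasso partial-correlation networks with
    case-dropping centrality-stability coefficients, edge-weight bootstraps and
    Louvain communities, and configuration-alignment indices (first canonical
    correlation, RV coefficient, Procrustes similarity, distance correlation,
    Mantel permutation test). Includes a synthetic-cohort generator with known
    latent five-domain structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
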
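Package: ccmweb
Title: Multiscale Causal Networks for Ecological Time Series via Convergent Cross Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to infer and compare dynamic-causal interaction networks from
    ecological abundance time series at multiple temporal and taxonomic scales.
    Implements convergent cross mapping (CCM) from first principles (time-delay
    embedding, simplex-weighted cross-map prediction), two significance
    procedures (a lag-maximized cross-correlation baseline and seasonal
    within-month surrogates), functional-group aggregation, and network
    comparison across timescales. Ships two simulators used to study
    scale-dependence of inferred links: a three-trophic-level individual-based
    automata model with fast and slow interaction channels, and a
    connectance-parameterized coupled logistic predator-prey model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
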
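Package: flcdyn
Title: Total FLC Expression Dynamics and Vernalization Requirement in
    Brassica napus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the decline of FLOWERING LOCUS C (FLC) expression during
    vernalization in the allopolyploid Brassica napus, where nine FLC
    paralogues jointly set the floral-repression dose. Fits exponential decay
    models (with and without a nonzero floor) to replicate-level TPM time
    series by nonlinear least squares, selects between the nested models by
    an F-test, and bootstraps confidence intervals for the decay rate.
    Predicts vernalization requirement as the day total FLC expression
    crosses a floral-competence threshold under three decay-rate scenarios,
    clusters genes and accessions by expression strategy, simulates read
    mis-assignment among near-identical paralogue references, and computes
    coding-sequence divergence statistics (pairwise identity, Nei-Gojobori
    dN/dS, neighbour-joining trees with bootstrap support). Includes a
    synthetic-data generator reproducing the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
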
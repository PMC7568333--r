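Package: pterochron
Title: Phylogenomic Divergence-Time Workflows for Pteropods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a pteropod phylogenomic dating workflow: filtering of
    index-hopping cross-contamination in multiplexed transcript expression
    tables, ortholog supermatrix construction with occupancy filtering,
    column trimming and bootstrap-informativeness gene ranking, Bayesian
    relaxed-clock divergence-time estimation on a fixed topology (uncorrelated
    gamma, autocorrelated lognormal and CIR rate processes; birth-death,
    uniform and Dirichlet node-age priors; fossil calibrations as soft minimum
    bounds), and fossil diversity-through-time curves from species occurrence
    databases. A synthetic-data generator emulates every input so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
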
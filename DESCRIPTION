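Package: arealclust
Title: Focused Spatial Cluster Detection for Areal Disease Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Four focused cluster-detection procedures for areal disease
    counts: the circular and flexible spatial scan statistics with Monte
    Carlo inference, Bayesian disease mapping with a proper conditional
    autoregressive (CAR) prior fitted by a bespoke Metropolis-within-Gibbs
    sampler, and data-cloning maximum likelihood with relative-risk
    prediction intervals.  Includes internal indirect standardization of
    expected counts over year, age and sex strata, and a synthetic-data
    generator emulating a 67-region health-district study design with
    planted clusters, so the full pipeline is testable without
    confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rjags
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
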
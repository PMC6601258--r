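Package: netscan
Title: Network Scan Statistics for Spatial Count Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detection and characterization of spatial and spatiotemporal
    hot spots in county-level count data. Scores connected county clusters
    with the Kulldorff Poisson likelihood ratio and an expectation-based
    Poisson statistic, searches for the best-scoring connected cluster
    exactly on small graphs and heuristically at scale, assesses
    significance by Monte Carlo replication conditioned on total event
    counts, provides a circular-window baseline scan, characterizes
    anomalous counties by stepwise-AIC logistic regression with odds
    ratios, profiles top-decile providers by specialty, and generates
    synthetic county/provider data with injected clusters for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
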
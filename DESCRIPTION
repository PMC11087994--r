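Package: dstam
Title: Dynamic Spatial-Temporal Accessibility to Urban Health Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures dynamic spatial-temporal accessibility (DSTAM) of an
    urban population to scarce health services such as haemodialysis.
    Clusters the 168 hour-of-week slots into ordered traffic congestion
    levels, reconstructs the full origin-destination travel-time tensor
    from a reduced sample by per-level regression on free-flow times,
    computes cumulative-opportunity coverage at travel-time thresholds
    with sociodemographic equity disaggregation, estimates patient demand
    from prevalence, and sites one or two new services by maximal covering
    location optimisation (exhaustive and genetic-algorithm solvers).
    Includes a seeded synthetic-city generator emulating a large,
    congested, income-stratified city for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
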
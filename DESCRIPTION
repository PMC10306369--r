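Package: selfkit
Title: Inferring Transitions to Self-Fertilization from Genome-Wide Polymorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference toolkit for dated transitions from
    outcrossing to self-fertilization. Provides coalescent simulators with
    time-varying selfing rates (a pairwise sequentially Markov simulator, a
    multi-sample simulator built on a selfing time rescaling, and a forward
    Wright-Fisher oracle), T_MRCA-segment analytics, window-based
    transition-matrix summary statistics together with the site frequency
    spectrum and linkage-disequilibrium decay, and rejection approximate
    Bayesian computation with partial least squares dimension reduction for
    model choice (transition to selfing versus population-size change) and
    for estimating the age of the transition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    withr,
    vcfR,
    mixOmics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr
Config/testthat/edition: 3
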
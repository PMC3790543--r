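Package: sefrisk
Title: Phylogenetic Risk Assessment for Ecosystem Function Vulnerability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the vulnerability of ecosystem properties and
    services to environmental change from the phylogenetic structure of
    species' effect and response functions. A Specific Effect Function (SEF)
    is the per-unit capacity of a species to influence an ecosystem property;
    a Specific Response Function (SRF) is its ability to maintain or enhance
    its population under a specified driver of change. The package estimates
    phylogenetic signal in SEFs and SRFs (maximum-likelihood Pagel's lambda
    for continuous variables, the Fritz-Purvis D statistic for binary ones),
    models SEFs from functional traits by phylogenetic generalized least
    squares, assesses the SEF-SRF correlation both phylogenetically and
    nonphylogenetically, classifies the system into one of four scenario
    quadrants, assigns an ordinal risk of function loss, and simulates
    trait-based driver filtering with before/after SEF summaries and retained
    phylogenetic diversity. A synthetic-data generator (pure-birth trees,
    lambda-structured Brownian traits, threshold binary traits, SEF/SRF pairs
    with controlled cross-correlation) supports calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phytools,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
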
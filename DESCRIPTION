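Package: kinomescanr
Title: Quality Control, Bayesian Kd Inference and Selectivity Analysis for
    Kinome-Wide Competition-Binding Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing kinome-wide competition-binding screens of
    the KINOMEscan/scanMAX type, in which each compound-kinase pair is
    reported as a percent-of-control value at a small number of
    concentrations. Provides a synthetic data generator with known ground
    truth, five-class quality control of dose-response curves, Bayesian
    hierarchical estimation of dissociation constants and Hill slopes with
    censoring outside the tested concentration range (including a reduced
    two-dose mode), selectivity metrics (target affinity spectrum bins,
    partition index, concentration- and target-dependent selectivity, and a
    chemical-probe filter), kinome coverage and promiscuity statistics,
    screening-design evaluation (single-dose percent-control cutoffs and
    two-dose versus four-dose agreement), affinity-profile clustering, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    jsonlite,
    mclust,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
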
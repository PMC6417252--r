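Package: wrkyBN
Title: Bayesian Network Modeling and Utility-Based Intervention Ranking
    for the WRKY Drought-Response Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the ABA-induced WRKY transcription-factor signaling
    pathway of Arabidopsis as an eight-node binary Bayesian network.
    Provides preprocessing of gene-expression matrices (normalization,
    mean/median binarization, multi-dataset aggregation), rule-based
    synthesis of protein-complex node states from observed transcription
    factor data, conjugate Beta-Binomial and maximum-likelihood estimation
    of all conditional probability tables, exact joint and marginal
    inference by enumeration, and ranking of single-node
    activation/inhibition interventions by expected utility against a
    utility table over the drought-response gene's regulators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
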
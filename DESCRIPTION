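Package: filterDCA
Title: Interpretable Supervised Inter-Domain Contact Prediction from
    Coevolutionary Couplings
Version: 0.1.0
Authors@R:
    person("filterDCA", "Developers", email = "filterdca-dev@example.org",
           role = c("aut", "cre"))
Description: Post-processes direct coupling analysis (DCA) score matrices for
    pairs of interacting protein domains. Local windows of the DCA score map
    are correlated against a bank of secondary-structure-derived contact
    pattern filters (helical periodicity, parallel and anti-parallel strand
    diagonals) obtained by averaging and 3-means clustering of contact-map
    windows. The raw coupling score and the best filter correlation are fused
    by an L2-regularised logistic regression into a calibrated contact
    probability. Includes contact-map derivation from coordinates, a synthetic
    benchmark generator, positive-predictive-value and calibration evaluation,
    and a command line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
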
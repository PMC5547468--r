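Package: beaconrisk
Title: Membership-Inference Risk Analysis and Mitigation for Genomic Beacon Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for the likelihood-ratio
    membership-inference attack on genomic beacon services (allele-presence
    yes/no query servers). Generates synthetic populations under the standard
    neutral site-frequency spectrum, builds beacon databases from genotypes or
    VCF, computes the closed-form risk profile of a beacon (beta fit of the
    frequency spectrum, the D_N no-allele probability, the expected query
    budget and the decision threshold), runs the attack against seeded cohorts
    of members, non-members and relatives, and evaluates two randomized
    perturbation defenses (random position elimination and biased randomized
    response) together with their differential-privacy guarantee and the
    privacy-utility tradeoff.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
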
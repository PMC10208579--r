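Package: stripepi
Title: Environment-Dependent Epistasis in a Synthetic Stripe-Forming Gene
    Regulatory Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for environment-dependent epistasis in a
    three-node incoherent-feedforward-loop gene regulatory network that
    forms a stripe of reporter expression along an arabinose gradient.
    Provides enumeration of single, pairwise and triplet cis-regulatory
    mutant genotypes; a steady-state Hill-function circuit simulator with
    replicate noise, a multiplicative-null mode and injectable
    interactions; plate-reader normalization (blank/OD correction,
    wild-type scaling, growth-based replicate QC); multiplicative-model
    epistasis with higher-order decomposition, error propagation, summary
    t tests and false-discovery-rate control (Storey q-values,
    Benjamini-Hochberg, two-stage Benjamini-Krieger-Yekutieli);
    classification of epistasis into magnitude, sign and reciprocal-sign
    types and inducer-dependence categories; and projection of expression
    patterns into a two-dimensional phenotype space with quadrant classes
    and distances to the wild type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    tidyr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
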
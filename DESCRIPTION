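Package: gpmixnet
Title: Multi-Trait Deep Learning Genomic Prediction for Mixed Phenotypes
Version: 0.1.0
Authors@R: person("gpmixnet", "developers", email = "gpmixnet@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction with densely connected neural networks for
    mixed continuous, binary and ordinal traits. Builds genomic features from
    marker dosages via the genomic relationship matrix and its Cholesky
    factor, optionally including genotype-by-environment interaction through
    a Kronecker-structured design, trains multi-output networks (MTDLMP) or
    univariate networks (UDL) with per-trait-type output activations, tunes
    epochs and hidden units by inner-validation grid search, and evaluates
    prediction accuracy under fivefold CV2 cross-validation with Pearson
    correlation and percentage of cases correctly classified. Includes a
    simulator for marker and mixed-phenotype data with configurable
    heritability, genetic correlation and G-by-E variance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
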
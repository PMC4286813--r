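Package: lrpstage
Title: Stage-Distribution Statistics for Lateral Root Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical tools for lateral root (LR) phenotyping in seedling
    assays. Implements the descriptive phenometrics of root-system
    architecture (emerged-LR density per cm of primary root, branching-zone
    density, stage-distribution summaries with proportion standard errors,
    pairwise density t-tests) and a multinomial generalized likelihood-ratio
    (G) test comparing lateral root primordium (LRP) stage-count distributions
    between two genotypes, with Monte Carlo p-values from a
    parametric-randomization null, an exact-enumeration oracle for small
    tables, and type-I error / power calibration. A continuous-time
    stage-progression simulator generates synthetic whole-root staging surveys
    and gravistimulation-induced single-LRP time courses with
    genotype-dependent progression rates, including maximum-likelihood
    recovery of the progression-rate multiplier from snapshot data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
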
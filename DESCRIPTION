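Package: qpcrEff
Title: Predicting and Estimating Quantitative PCR Amplification Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with quantitative PCR (qPCR) amplification
    efficiency. Extracts the amplicon- and primer-level sequence features
    known to influence efficiency (length, G+C content, homopolymer
    repeats, reverse-complement palindromes, melting temperature, 3'
    termini, and triplet-based self-complementarity and primer-dimer
    hybridization scores), estimates per-reaction efficiency from raw
    fluorescence amplification curves by sigmoid modelling and
    second-derivative analysis, fits a generalized additive model with
    three bivariate smooths to predict efficiency from sequence features,
    provides a univariate asymptotic rank-test battery with effect-size
    conversions (Cohen's d, Hedges' g, log odds), and evaluates predicted
    efficiency as a binary classifier of PCR success with ROC and
    precision-recall curves. A synthetic-data generator emulating a
    multi-species 90-primer-pair efficiency study makes the whole pipeline
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    dplyr,
    mgcv,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
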
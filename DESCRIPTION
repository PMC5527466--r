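Package: screenkit
Title: Analysis of Plate-Based RNAi Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide siRNA reporter screens run in
    microtitre plates: per-plate log2 normalization to designated
    reference wells, robust Z-scoring against the library-well
    distribution, fixed-threshold and control-anchored hit calling with
    replicate-consistency rules, viability counterscreen scoring and
    toxicity stratification of luminescence-decreasing hits, siRNA pool
    deconvolution confirmation (fold induction, k-of-n consistency),
    delta-delta-Ct qPCR quantification with knockdown-phenotype
    concordance classification, rank-based gene-set shift tests
    (exact and approximate Mann-Whitney, Monte-Carlo Dunnett
    many-to-one comparisons), and a fully parameterized synthetic
    screen generator with ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
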
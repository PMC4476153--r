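Package: neighborz
Title: Correlated Evolution of Gene Expression Among Genomic Neighbors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether evolutionary change in gene expression
    is genomically clustered ("expression piggybacking"). Reconstructs the
    expression level at the human-chimp ancestor under a Brownian-motion
    trait model on a five-primate tree (closed-form conditional Gaussian and
    MCMC), summarises per-gene divergence as a variance-scaled Z score with a
    per-tissue median correction, and provides the spatial statistics used to
    interrogate it: neighbor Z correlations, sign-run and cluster-size
    randomization tests, distance-decay correlograms with Monte Carlo
    envelopes, cross-tissue concertedness and tissue-specific-upregulation
    tests, chromatin-mark overlap chi-squares, and standard-major-axis
    residual analyses of sex-biased expression change. A synthetic-data
    generator with known ground truth (blocked human-branch shifts on a
    chromosome-ordered gene map, plus coupled annotation tracks) supports
    calibration and power analysis of every test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phytools,
    withr
Config/testthat/edition: 3
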
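Package: attractorscape
Title: Attractor-Landscape Analysis of Time-Course Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing rapid transcriptome-wide state transitions
    from time-course RNA-seq count matrices. Implements TPM normalisation and
    distribution-based expression filtering, maximum-likelihood fitting and
    AIC comparison of candidate expression distributions, temporal correlation
    metrics (Pearson, Spearman, biweight midcorrelation, and a bias-corrected
    histogram mutual-information correlation), deviation-based correlation
    landscapes with kernel-density attractor-basin boundary extraction,
    classification of rank-ordered transcriptomic elements into attractor and
    non-attractor gene sets, principal-component trajectory validation, Ward
    temporal clustering with correlation-threshold refinement, and a seeded
    synthetic time-course generator with ground-truth labels for recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    fitdistrplus,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
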
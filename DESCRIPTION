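Package: condensr
Title: Quantification of Protein Condensate Dynamics, Puncta Morphometry and
    Aggregation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studies of protein liquid-liquid phase
    separation and aggregation. Provides fluorescence recovery after
    photobleaching (FRAP) quantification (rigid stack registration, FRAP-ROI
    construction by mask arithmetic, two-anchor trace normalization, and
    bounded single-exponential recovery fitting), puncta segmentation and
    morphometry (area, circularity, roundness, aspect ratio, solidity,
    corrected total fluorescence statistics), maximum-likelihood fitting of
    univariate normal mixtures to punctum-area distributions by
    expectation-maximization, percent-insoluble quantification from
    densitometry tables, thioflavin-T aggregation-kinetics half-transition
    times, and rank-based group comparisons (Kruskal-Wallis with Dunn's
    post-hoc, one-way ANOVA with Bonferroni). A synthetic-data generator
    produces every input the pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    withr,
    jsonlite,
    tiff,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
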
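Package: ionoquant
Title: Segmentation, Quantification and Counting Statistics for
    Neuromast Ionocyte Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying neuromast-associated
    ionocytes in zebrafish confocal data: 3D instance segmentation of
    reporter-labelled cells by slice-wise tracking with merge-event
    splitting (white top-hat background subtraction, Gaussian smoothing,
    fixed-grey-value thresholding and Euclidean-distance-transform mask
    shrinking), per-cell and per-ROI fluorescence quantification
    (including rolling-ball subtraction on maximum projections and raw
    brightest-slice paired asymmetry), ionocyte classification and
    counting conventions (progenitor units, per-larva averages,
    neuromast frequencies, per-replicate control normalization), and an
    adaptive statistical comparison scheme (normality-gated t or
    Mann-Whitney tests, paired Wilcoxon, ANOVA or Kruskal-Wallis with
    Dunnett or Dunn post-hoc tests). A synthetic-data module generates
    ground-truthed confocal-like stacks and simulated count experiments
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    multcomp,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
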
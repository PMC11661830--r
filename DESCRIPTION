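Package: iEEGComplexity
Title: Visual Complexity of Intracranial EEG Time-Frequency Images for
    Epileptogenic-Zone Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts interictal intracranial EEG (iEEG) signals into fixed-grid
    Morlet time-frequency images, quantifies each image's visual complexity as
    layer-wise unsupervised activation energy (UAE) of a VGG16-style
    convolutional network, and identifies low-complexity points of interest via
    extreme-value-distribution thresholds and a grouped cross-validated linear
    support vector machine. Points of interest are scored by their Euclidean
    distance to a resection mask in patient-MRI space. Includes a synthetic
    cohort generator (pink-noise background plus transient broadband
    epileptiform discharges with electrode geometry and a resection volume),
    EDF/TSV/NIfTI input-output, and the accompanying statistical comparisons
    (Wilcoxon signed rank, Cohen's d, Bonferroni).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    RNifti,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
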
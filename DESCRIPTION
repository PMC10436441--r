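Package: pdmtools
Title: Protein Profiling and Drug-Response Analysis for Patient-Derived Microtumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for patient-derived microtumor (PDM)
    studies in breast cancer: bead-array western blot (DigiWest-style) signal
    processing from raw molecular-weight-fraction fluorescence to a normalized,
    median-centered log2 expression matrix; cytotoxicity-based drug responder
    classification with robust outlier exclusion and a REML mixed-effects model;
    color-deconvolution-based stain quantification of brightfield images; and
    the downstream statistics (matched-pair Pearson correlation, Welch volcano
    with two-stage adaptive FDR, hierarchical clustering, marker-panel tests,
    and simple logistic response models). Includes seeded synthetic-data
    generators with ground truth so every stage is testable without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
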
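Package: mohsmap
Title: Tile-Based Tumor Localization in Mohs Frozen-Section Microscope Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Localizes nonmelanoma skin-cancer regions in microscope
    field-of-view images of Mohs frozen sections with a tile-based
    classification pipeline: square-tile decomposition with a tumor-area
    labeling rule, a convolutional tile classifier trained with
    augmentation and early stopping, a two-stage weakly supervised
    training procedure with confidence filtering, sliding-window assembly
    of tumor probability (saliency) maps, and a pixel-level evaluation
    suite (average precision, AUROC, highest Dice coefficient, folds
    enrichment of precision) with patient-level leave-one-out
    cross-validation, bootstrap confidence intervals, paired Wilcoxon
    comparisons, and Fleiss' kappa interrater agreement on segmentation
    masks. Includes a synthetic frozen-section image generator with known
    tumor masks so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Software, BiomedicalInformatics
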
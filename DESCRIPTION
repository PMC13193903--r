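Package: ifcmorph
Title: Label-Free Bovine Sperm Morphology Analysis for Imaging Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable pipeline for automated classification of bovine sperm
    morphology from label-free brightfield imaging flow cytometry (IFC)
    frames. Provides a synthetic single-cell image generator with a realistic
    bulls/ejaculates/files acquisition hierarchy and controllable breed and
    preparation-condition domain shifts; quality-control filtering and image
    standardization; stratified quota labeling, class-balanced batch sampling
    and fixed stratified splits; linear-probe (LP) and linear-probe plus
    fine-tuning (LP-FT) training of a compact CPU-scale convolutional
    classifier; evaluation statistics including leave-one-breed-out folds,
    labeled-data-fraction learning curves, cross-condition and cross-breed
    generalization matrices with percentage-point gap arithmetic, and
    hierarchical cluster bootstrap confidence intervals; and morphology
    profiling reports for unlabeled image pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
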
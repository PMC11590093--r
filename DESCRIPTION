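Package: adhekin
Title: Single-Cell Adhesion Kinetics from Resonant Waveguide Grating Biosensor Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for label-free single-cell evaluation of
    resonant waveguide grating (RWG) biosensor adhesion recordings. The package
    splits 240 x 320 wavelength-shift mosaics into 80 x 80 wells, trims
    recordings to adhesion onset using pipetting gaps in the instrument
    timeline, applies offset, outlier and pseudorandom background correction,
    registers biosensor wells to high-resolution phase-contrast microscope
    segmentation masks with a scale-plus-translation transform, extracts
    single-cell (t, 8, 8) video samples by mask-cover or watershed
    segmentation, assembles stratified, oversampled and pixel-wise
    standardized datasets, classifies cell types with four small
    spatio-temporal neural networks (CNN, ResNet, DenseNet, CNN-LSTM), and
    evaluates segmentation (detection error, Dice dissimilarity) and
    classification (accuracy, F1, AUC, AUC-PR, confusion matrices, t-SNE
    embeddings). A synthetic experiment generator with known ground truth
    makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
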
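Package: tracell
Title: Detection of Rare TRA-1-60 Positive / CD45-Low Cells in PBMC
    Immunofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for screening peripheral blood
    mononuclear cell (PBMC) slides for rare cells positive for the embryonic
    stem-cell surface marker TRA-1-60 with near-background CD45 levels.
    Nuclei are segmented from the DAPI channel (Gaussian smoothing, top-hat
    background subtraction, Otsu thresholding, median-gated watershed
    splitting), per-cell regions are built by Rosin thresholding, dilation
    and nearest-seed label propagation, and the TRA-1-60 detection threshold
    is calibrated per patient from secondary-antibody-only negative controls
    so that controls yield zero detections. Per-patient measures (percentage
    of TRA+ cells per field, TRA+/CD45-low cells per 1000 cells, normalized
    CD45 intensity difference between TRA+ and TRA- cells) feed ROC
    diagnostics with Hanley-McNeil or DeLong confidence intervals. A
    synthetic multi-channel slide generator with per-cell ground truth
    supports end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    pROC,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
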
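Package: eusei
Title: Quantitative Elasticity Extraction and Risk Stratification for
    EUS Elastography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies dual-panel endoscopic ultrasound elastography
    (EUS-E) frames of gastrointestinal stromal tumors. Splits a frame at
    the central marker line, transfers a B-mode lesion mask onto the
    colour elastogram, restricts quantification to the solid lesion
    component, averages the colour pixels and projects the mean colour
    onto a blue(stiff)-to-red(soft) colormap by minimum HSV distance to
    obtain a 0-1 elasticity index. Patient-level tools provide ROC/AUC
    analysis with Youden-optimal cutoffs, diagnostic metrics with
    confidence intervals, Spearman correlation, logistic odds ratios and
    cohort summaries, plus segmentation evaluation (Dice, IoU, detection
    precision/recall). A calibrated synthetic phantom generator emulates
    the dual-panel geometry and group elasticity distributions so every
    stage is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
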
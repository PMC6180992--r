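Package: adipoquant
Title: Automated Abdominal CT Adipose Quantification and Phenome-Wide
    Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies visceral, subcutaneous, and total adipose tissue
    (VAT, SAT, TAT) on axial abdominal CT slices with an unsupervised
    greedy active-contour ("greedy snake") pipeline: body segmentation by
    Hounsfield thresholding and morphological opening, Moore-neighbor
    boundary tracing, discrete greedy snake refinement of the outer body
    contour, pressure-driven snake contraction to the abdominal cavity
    contour, and fat classification in the (-190, -30) Hounsfield window.
    Includes a seeded synthetic CT phantom generator with exact ground
    truth, readers for single-frame CT DICOM and a plain-text array
    fixture dialect, and a phenome-wide association (PheWAS) module:
    ICD-9 visit-count case/control construction, Box-Cox normalization,
    outlier cleaning of clinical labs, logistic and linear association
    models with age/sex covariates, Bonferroni and Benjamini-Hochberg
    multiple-testing control, and a synthetic EHR generator for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mgcv,
    jsonlite,
    data.table,
    stats,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
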
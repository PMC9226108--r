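Package: sonotkv
Title: Automated Total Kidney Volume from Tracked 3D Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end measurement of total kidney volume (TKV) in
    autosomal-dominant polycystic kidney disease from tracker-aligned 3D
    B-mode ultrasound stacks. Provides a synthetic sector-scan phantom
    generator with analytic ground truth, slab-based preprocessing, rotation
    and elastic-deformation augmentation, a six-level 2D U-Net trained with
    the Dice loss (implemented natively with Rcpp), volumetry and interscan
    variability, a seven-metric segmentation evaluation panel, percent-scale
    Bland-Altman method comparison, Mayo imaging classification of ADPKD
    severity, and cohort demographic summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
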
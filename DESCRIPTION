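Package: gsosScreen
Title: Polygenic Pre-Screening for Osteoporotic Fracture Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to train a sparse polygenic score for heel ultrasound speed of
    sound (gSOS) by LASSO regression over p-value-thresholded SNP sets with
    held-out model selection, and to evaluate its use as a pre-screening gate in
    a staged FRAX-based fracture risk screening algorithm (NOGG-style).
    Includes a synthetic cohort generator with LD-structured genotypes and
    FRAX-style risk factors, a transparent parametric surrogate for 10-year
    major osteoporotic fracture probability, per-SNP association testing with
    greedy LD clumping, screening decision traces, and performance reporting
    (sensitivity, specificity, predictive values, and screening-test burden).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
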
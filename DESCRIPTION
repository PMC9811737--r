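Package: prognokin
Title: Prognostic Gene Signatures and Radiotracer Uptake Kinetics for
    Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds progression-free-survival genetic scores from
    standardized gene expression by consensus machine-learning feature
    ranking (Random Forest and fuzzy-C-means-thresholded Lasso over
    repeated event-rate-preserving splits), bootstrap-stabilized
    multivariable Cox regression, median-split Kaplan-Meier
    stratification, and optimism-corrected Harrell concordance.  Also
    analyzes in-vitro radiotracer time-activity curves from rotating-dish
    beta detectors: closed-system Patlak graphical analysis for
    irreversible FDG-like uptake and one-phase association fitting for
    saturable PSMA-like binding.  Includes calibrated synthetic cohort and
    curve simulators so the complete procedure is reproducible without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    minpack.lm,
    ranger,
    stats,
    survival,
    tools,
    utils
Suggests:
    e1071,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
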
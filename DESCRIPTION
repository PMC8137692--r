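Package: ctsarco
Title: CT Body Composition Quantification and Sarcopenia Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies body composition on computed tomography volumes by
    Hounsfield-unit tissue classification: single-slice skeletal muscle and
    fat areas at the third lumbar vertebra (skeletal muscle index, Prado
    low-muscle-mass classification) and multi-slice whole-body mass
    estimates (muscle, fat, lean, visceral and subcutaneous fat body mass)
    with extrapolation factors that correct for the limited scan field of
    view. Includes a labeled CT phantom generator and a survival-cohort
    simulator with known ground truth, plus the downstream prognostic
    workflow: nutritional indices, group comparisons, Kaplan-Meier and
    log-rank analysis, ROC-based optimal dichotomization of anthropometric
    markers, and univariate and stepwise multivariate Cox regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
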
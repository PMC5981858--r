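Package: tidybreathe
Title: Tidal Breathing Analysis and Locally Weighted Ridge-Logistic Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for screening compromised pulmonary function
    from restful (tidal) breathing flow signals. Provides a seeded simulator of
    tidal-breathing cohorts, breath-cycle segmentation with drift-free volume
    derivation, extraction of twelve physiological features (timing, peak flow,
    tidal volume and velocity descriptors), a from-scratch locally weighted
    learning classifier based on ridge-penalized local logistic regression that
    operates on raw, unnormalized features, and an evaluation harness with
    repeated stratified cross-validation, hold-out grid search, SMOTE
    augmentation, Fisher linear discriminant projection and the Friedman rank
    test for classifier comparison. All user-facing functions take and return
    tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
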
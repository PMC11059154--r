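Package: sloptim
Title: Snow Leopard Optimization with Fractional-Order Memory for Image
    Analysis Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Snow Leopard Optimization Algorithm (SLOA), a
    population metaheuristic with motion, preying, breeding and fatality
    phases, and its fractional-order extension (FO-SLOA) in which position
    updates carry a Grunwald-Letnikov weighted memory of recent accepted
    positions. Ships a classic analytic benchmark suite with a repeated-trial
    AVG/STD comparison harness, the preprocessing operators used in
    medical-image classification pipelines (fuzzy-entropy adaptive median
    denoising, brightness-preserving bi-histogram equalization, SMOTE class
    balancing), a weighted composite objective for hyperparameter tuning of a
    compact classifier, the six standard confusion-matrix metrics, and
    deterministic generators for knee-MRI-like phantom images and imbalanced
    tabular datasets. All user-facing functions take data frames or plain
    matrices and return tibbles, with broom-style tidy()/glance() and
    ggplot2 autoplot() methods for fitted optimizer objects.
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
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
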
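Package: mavemeld
Title: Integrate Multiplexed Assays of Variant Effect and Calibrate
    ACMG/AMP Functional Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonizes per-variant functional score sets from multiple
    multiplexed assays of variant effect (MAVEs) into a single
    variant-by-assay matrix, integrates them into one functional score or
    class per variant (principal components, K-means clustering, Gaussian
    naive Bayes, random forests), evaluates individual and integrated
    scores against a clinical truth set of benign and pathogenic variants
    (sensitivity, specificity, PPV, NPV, dynamic range), and converts
    classifier concordance into OddsPath likelihood ratios and ACMG/AMP
    PS3/BS3 evidence strengths. Includes a synthetic multi-assay deep
    mutational scanning generator emulating paired loss-of-function and
    dominant-negative selections with synonymous and nonsense controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
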
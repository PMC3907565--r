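Package: perimix
Title: Variational Bayesian ICA Mixture Modelling of Visual-Field Perimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised analysis of Frequency Doubling Technology (FDT)
    perimetry fields with a variational Bayesian independent component
    analysis mixture model. Fields (52 threshold sensitivities on the 24-2
    test pattern plus age) are clustered into sub-populations, each carrying
    its own set of statistically independent axes; automatic relevance
    determination and knee-point selection prune the axis sets, and ordered
    glaucomatous defect patterns are generated along each retained axis.
    Includes a calibrated synthetic FDT cohort generator, a candidate-model
    grid search with a specificity-goal selection rule, cluster evaluation
    against instrument labels, and total-deviation-style pattern rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
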
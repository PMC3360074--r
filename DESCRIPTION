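Package: afield
Title: Generative Association-Field Models of Contour Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying human contour integration as probabilistic
    inference. Contours are sampled from a Markov process whose transition
    density is an association field (a radial decay times a product of
    von Mises factors encoding co-circularity and curvature), hidden among
    distance-matched distractor fields, and detected by an ideal or
    constrained observer that accumulates starting-edge likelihoods by
    iterated matrix multiplication. Includes two-alternative forced-choice
    simulation, the exact independence null for counts of identical
    responses between observers, a mid-p excess-correlation statistic,
    leave-one-out prototype observers, permutation significance thresholds,
    and a four-parameter grid search for the observer model that best
    reproduces a set of reference decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
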
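Package: tomscale
Title: Guttman-Scale Analysis of a Theory-of-Mind Task Battery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing ordered binary task batteries of the
    Wellman-Liu Theory-of-Mind type in school-age children. Provides
    child-level scoring with permutation tests for demographic and
    temperament correlates, a set-inclusion scaling statistic (successive
    violation counts and their sum) with shuffle-null significance, a
    covariate logistic model with factor-removal likelihood-ratio tests,
    and per-task Pointwise/Markov/Cumulative model-set comparisons that
    quantify the Guttman-scale property. Includes a calibrated synthetic
    cohort generator (four-parameter IRT-style slip/guess noise over a
    latent ability) for calibration, power and recovery studies, and a
    deterministic fixture matrix reproducing the published aggregate
    pass and violation counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
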
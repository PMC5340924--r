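Package: catgrm
Title: Graded Response Model Calibration and Computerized Adaptive
    Testing Simulation for Ordinal Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-stage psychometric pipeline for short ordinal symptom
    questionnaires scored 0/1/2: classical descriptives with Cronbach alpha,
    item response theory assumption checks (polychoric one-factor fit
    indices, residual-correlation local-dependence screening, Loevinger
    scalability and rest-score trace lines), marginal maximum likelihood
    calibration of Samejima's graded response model, differential item
    functioning screening via nested ordinal logistic regressions with a
    pseudo R-squared change criterion, and a post-hoc computerized adaptive
    testing simulation with expected-a-posteriori trait estimation, maximum
    Fisher information item selection and dual stopping rules. Includes a
    synthetic-data generator that emulates a four-scale, 50-item
    questionnaire cohort so the whole pipeline is testable without patient
    data.
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
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
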
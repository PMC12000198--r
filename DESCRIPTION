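Package: misscr
Title: Kelley's Paradox and Strength Skewness in Miss versus Correct-Rejection Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether contrasting recognition-memory misses
    against correct rejections equates true memory strength. Provides a
    classical-test-theory simulator of Kelley's Paradox (regression to the
    mean under measurement error), closed-form and Monte-Carlo calculators
    for the expected true strength of items whose observed strength falls in
    a truncated response window (including truncated-normal skewness
    diagnostics), a synthetic generator for a recognition plus
    two-alternative forced-choice experiment, and the complete analysis
    pipeline for such experiments: exclusion filters, rating distributions,
    d-prime and criterion estimation by maximum likelihood, accuracy tests,
    split-half reliability, and random-intercept logistic modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
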
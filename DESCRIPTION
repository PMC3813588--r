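Package: cogineq
Title: Decomposition of Socioeconomic Inequality in Children's Cognitive
    Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures household-expenditure-related inequality in children's
    cognitive test scores with the relative concentration index (twice the
    weighted covariance between the age-standardized score and the fractional
    expenditure rank, divided by the mean score), attaches delta-method
    standard errors, decomposes the index into elasticity-weighted contributor
    shares via weighted least squares (Wagstaff-type decomposition), and
    splits the change in inequality between two survey rounds into
    changing-inequality and changing-elasticity terms (Oaxaca-type
    decomposition). Includes Hozo mean/SD recovery from median and range for
    age-specific z-scoring, a conjugate Gibbs sampler for equal-tail credible
    intervals on contribution shares, chained-equations multiple imputation
    pooled by Rubin's rules, and a seeded synthetic household-survey generator
    emulating the Indonesia Family Life Survey structure.
License: MIT + file LICENSE
Encoding: UTF-8
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
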
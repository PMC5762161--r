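Package: uoa
Title: Unit-of-Analysis Aware Statistics for Nested Laboratory Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multilevel laboratory data in which the
    experimental unit (the subject) carries multiple samples and replicate
    measurements, so that naive observation-level analyses pseudoreplicate
    and inflate the false-positive rate. Implements the full analysis
    ladder from first principles: naive pooled two-sample t-tests,
    subject-summary t-tests, restricted maximum likelihood (REML) fitting
    of nested Gaussian linear mixed models with stratum degrees of
    freedom, binomial logistic mixed models with a subject random
    intercept via Laplace or adaptive Gauss-Hermite quadrature,
    intraclass-correlation and design-effect calculators, sample-size
    inflation for clustered designs, and a Monte-Carlo engine measuring
    type-I-error inflation and efficiency of each analysis. Ships two
    fully worked example datasets (lymph-node sizes and binomial
    lymph-node counts from a radiotherapy study).
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
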
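Package: matrixhmm
Title: Parsimonious Hidden Markov Models for Matrix-Variate Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hidden Markov models for balanced four-way longitudinal data, where
    each of I units is observed as a P x R matrix at T occasions. Each hidden
    state carries a matrix-normal density whose row and column covariance
    matrices are constrained through the eigen (volume/shape/orientation)
    decomposition, giving a family of 98 parsimonious models. Provides maximum
    likelihood estimation by an expectation-conditional maximization algorithm
    with scaled forward-backward recursions, closed-form, eigenvalue and
    minorization-maximization covariance updates, short-EM initialization,
    BIC-based model selection over the family, posterior (local) decoding, a
    chi-squared test of geometric sojourn times with Holm adjustment, and a
    simulator for the whole family.
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
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
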
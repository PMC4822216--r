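Package: qpcreff
Title: Precise and Robust Assessment of qPCR Amplification Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating real-time PCR amplification efficiency from
    standard curves built on serial dilution series. Provides ordinary
    least-squares fitting of quantification cycle (Cq) values against log10
    relative concentration, conversion of the slope to efficiency with
    delta-method standard errors and t-based confidence intervals, Monte Carlo
    and exhaustive subsampling of technical replicates to quantify estimation
    imprecision, analysis of covariance (Type II sums of squares) to test
    whether efficiency differs across instruments or other factors, a
    stochastic serial-dilution simulator capturing pipetting error and Poisson
    molecule-sampling dropout, and propagation of efficiency misestimation
    into fold-change errors.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    car,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
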
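Package: remeth
Title: Remethylation Kinetics After Demethylating Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying de novo DNA remethylation kinetics in
    cancer cell lines after treatment with a demethylating agent such as
    5-aza-2'-deoxycytidine. Fits a delayed hyperbolic-tangent recovery
    curve to percent-methylation time series, classifies experimental
    runs, screens all pairs of fitted and directly measured quantities
    for Pearson and Spearman correlations, simulates a mechanistic
    negative-feedback model of methyltransferase regulation that
    distinguishes CpG-island methylator phenotype (CIMP) cells from
    non-CIMP cells, and estimates cell division and death rates from
    live/dead cell counts. Includes a seeded synthetic-data generator
    that emulates the statistical structure of such experiments so the
    whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
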
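Package: melpower
Title: Virtual Melatonin Suppression Experiments and Power Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates virtual laboratory melatonin suppression experiments
    from a stochastic population model of individual light dose-response
    curves. Fits the population model to per-individual raw estimates
    (kernel density over log10 ED50, Bayesian heteroscedastic regression of
    the log shape parameter, and a gamma population model of logit-scale
    measurement noise), calibrates per-individual noise levels against
    observed root-mean-square errors by root finding, and estimates
    Monte-Carlo statistical power for illuminance-comparison and
    light-sensitivity-intervention experiments under within- and
    between-subjects designs.
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
    KernSmooth,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
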
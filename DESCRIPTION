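Package: circmix
Title: Mixture Modelling of Continuous-Report Visual Working Memory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous-report (delayed estimation) visual
    working memory experiments. Provides circular summary statistics of response
    error (mean absolute error, resultant vector length, precision, bias),
    maximum-likelihood fitting of two- and three-component von Mises mixture
    models as well as slots and slots-plus-averaging capacity models via
    multi-start Nelder-Mead, information-criterion model comparison (AIC, AICc,
    BIC), a trial-level simulator of stimulus displays and model-based
    responses, and a simulation-study harness for parameter-recovery,
    parameter trade-off, and model-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
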
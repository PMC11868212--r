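Package: mossmap
Title: Bounded-Response Regression Mapping of Trace-Metal Concentrations in Forest Mosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping cadmium concentrations accumulated by forest
    mosses from biomonitoring networks. Implements a complementary log-log
    linear model for responses bounded in (0, Cd_max), staged covariate
    screening (zero-proportion and Spearman collinearity filters) followed
    by backward-forward AIC selection, Moran's I residual diagnostics with
    permutation tests, gridded prediction with delta-method standard
    deviations, an ordinary-kriging baseline on log concentrations, and
    leave-one-out cross-validation to compare predictors across
    biogeographical zones. Includes a synthetic-data generator emulating a
    moss biomonitoring study design so every stage is testable without the
    original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
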
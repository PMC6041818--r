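Package: healthineq
Title: Summary Measures of Health Inequality from Disaggregated Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-setting health-equity assessment from disaggregated
    indicator data. Reads and validates datasets in the standard 20-column
    upload template (CSV and Excel), partitions them into setting x year x
    source x indicator x dimension strata, and computes up to 15 summary
    measures of inequality (difference, ratio, population attributable
    risk/fraction, slope and relative index of inequality, absolute and
    relative concentration index, between-group variance, mean differences,
    indices of disparity, mean log deviation, Theil index) with applicability
    gated by dimension type and data availability. Includes graph-ready
    disaggregated-bar, trend and cross-setting benchmark tabulations, a
    synthetic-data generator emulating the template, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
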
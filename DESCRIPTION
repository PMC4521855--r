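Package: bushmeatTS
Title: Intervention Time-Series Analysis of Bushmeat Market Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for long-running wildlife-market carcass
    censuses: construction of monthly carcass rates from daily market
    records, seasonal ARIMA intervention (transfer-function) models of
    legislative and political shocks, loess trend-seasonal-remainder
    decomposition, per-period trend slopes with cross-taxon normalization,
    heteroscedastic two-factor generalized-least-squares ANOVA, bootstrap
    correlation intervals, and income-proxy regressions. Includes a
    seed-deterministic synthetic census generator with the same statistical
    structure, so every stage can be validated by parameter recovery when
    the underlying census is not public.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
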
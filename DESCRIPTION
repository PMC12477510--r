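Package: digimaturity
Title: Digital Maturity in Health Index Construction and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a composite digital maturity in health index for countries
    from 14 indicators grouped into 7 subcomponents (min-max or fixed-bounds
    normalization to 0-100, unweighted averaging), profiles missing data by
    WHO region and subcomponent, assigns quartile-based country maturity types,
    quantifies the association between digital maturity and primary health care
    performance with a Spearman rank correlation and confidence interval, and
    classifies countries into spending-efficiency quadrants from the residuals
    of log-expenditure regressions. Includes a synthetic country-table
    generator with a latent-capacity factor model so the full pipeline is
    testable without external data sources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
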
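Package: grnconsensus
Title: Consensus Gene Regulatory Network Construction from Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds consensus gene regulatory networks from a genes-by-conditions
    expression matrix. Per-edge connectivity is scored four ways (Pearson
    correlation, principal component regression, partial least squares, ridge
    regression), edge confidence is assessed by bootstrap resampling of
    conditions with per-edge t-statistics, p-values and tail-area false
    discovery rates come from a robust empirical null fitted to the
    t-statistics, and the four per-method p-values are combined with Fisher's
    method to select consensus edges. Includes a Gaussian graphical model
    simulator with planted network structure for validation, tidy accessors
    for all results, and a command-line pipeline that writes Cytoscape-loadable
    edge tables.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
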
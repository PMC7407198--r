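Package: radnet
Title: Radiality Network Analysis of Multiplex Cytokine and Phosphoprotein Tissue Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distance-based network analysis of multiplex immunoassay panels
    measured in periprosthetic knee tissue. Implements the full pipeline from
    long-format analyte measurements to per-network node significance calls:
    quantitation-limit censoring, 1.5xIQR outlier removal, per-depth location
    averaging, per-analyte maximum normalization, Euclidean-distance network
    construction, radiality centrality with normalization to the network mean,
    mean +/- SD significance classification, and cross-group comparison of
    significant nodes. Ships a synthetic-cohort generator that emulates the
    three-group (primary TKA, aseptic TKR, septic TKR), two-depth (ATL, RTL)
    study design, conventional two-way ANOVA with Bonferroni post-tests, a
    Pearson covariate confounder screen, and packaged reference fixtures of
    published normalized-radiality values for the six networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    emmeans,
    igraph,
    withr
Config/testthat/edition: 3
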
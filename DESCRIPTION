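Package: ednafish
Title: Trait-Guild Metrics and an eDNA-Adapted Predictive Fish Index for Rivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for eDNA-metabarcoding-based ecological assessment of river
    fish assemblages. Reads MOTU read-count and electrofishing catch tables,
    applies MOTU discard and trait-assignment rules, computes trait-guild
    community metrics and species-accumulation curves, fits reference-condition
    models of metric expectations from environmental descriptors, derives
    ecological quality ratios (EQR) and a predictive multimetric fish index
    with status classification, quantifies index uncertainty from replicate
    water samples and seasonal series, and provides method-comparison
    statistics together with a synthetic paired eDNA/electrofishing community
    generator for end-to-end validation.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
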
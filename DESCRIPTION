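Package: pcdea
Title: Output-Oriented DEA Benchmarking of Municipal Primary Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Benchmarks the efficiency of municipal primary health care with
    output-oriented, variable-returns-to-scale data envelopment analysis
    (the BCC envelopment model). Provides two built-in input/product models
    (health actions and health outcomes) with per-capita control products,
    sample-homogenization filters (participation, coverage, consistency,
    zero-input and percentile-trim exclusions), population-size
    stratification, a two-phase simplex solver with maximal-slack peer
    identification, reference-set classification, cross-model contingency
    tables, aggregate equiproportional product-expansion targets, and a
    synthetic municipal-data generator with a planted production frontier
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
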
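Package: bgyield
Title: Maize Yield Prediction and Trait Imputation with Bipartite Graph
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint imputation of missing trait measurements and prediction of
    maize yield from multi-environment trial tables. An observations-by-features
    table (meteorological aggregates, growth traits, yield) is represented as a
    complete weighted bipartite graph whose edge weights are the standardized
    cell values (zero where missing); stacked message-passing layers update
    node embeddings from incident edge embeddings and grow edge embeddings by
    concatenation, and a two-layer head decodes any cell from its endpoint
    embeddings. Training minimizes a gradient-harmonized L1 loss that tempers
    the influence of large residuals, which stabilizes fitting when planting
    locations contribute very unequal sample counts. Includes z-score and
    label-encoding preprocessing, daily-weather aggregation, mean/median/kNN
    imputation baselines, a random-deletion imputation benchmark, an ablation
    harness over depth/dropout/loss, and a synthetic multi-environment-trial
    generator with MCAR/MNAR missingness for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
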
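Package: causalmap
Title: Mechanistic Disease Maps from Causal Disease/Gene Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers mechanistic disease-disease associations from curated causal
    disease/gene annotation tables. Similarity of two diseases is scored by the
    number of shared causal genes against a degree-preserving random-set null:
    random gene sets are sampled so that each gene occurs with its observed
    association frequency, the mean overlap is modelled as a function of random
    set size by weighted least-squares regression with AIC model selection, and
    a Poisson upper-tail P-value is combined across the two per-disease models
    by their geometric mean. Downstream tools build thresholded disease maps
    with connected-component labelling and false-discovery-rate estimates, rank
    Gene Ontology terms across disease clusters by a preponderance statistic,
    predict causal genes by a two-step disease-then-gene similarity search with
    leave-k-out cross-validation, and rescore candidates on a molecular
    interaction network by random walk with restart. A synthetic-data module
    generates association tables with heavy-tailed gene degree distributions,
    planted disease modules, GO annotations and interaction networks so the
    whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
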
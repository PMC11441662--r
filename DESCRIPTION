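Package: overlapnet
Title: Edge-Centric Overlapping Modules in Weighted Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects overlapping functional modules in weighted brain
    networks with an edge-centric approach: retained connections become the
    vertices of a weighted edge (line) graph linked by Tanimoto similarity of
    modified connectivity profiles, edge modules are found by repeated
    seeded Louvain runs with co-occurrence consensus, and each node's module
    overlap is quantified by the normalized Shannon entropy of its edges'
    module affiliations.  Includes longitudinal mixed-effects age-effect
    estimation with AIC model selection and FDR correction, spatial-
    autocorrelation-preserving surrogate map tests, cross-validated linear
    support vector regression pipelines (age from nodal entropy maps,
    entropy maps from structural features), and synthetic-cohort generators
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
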
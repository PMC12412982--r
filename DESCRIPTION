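Package: bioglgcn
Title: Biological Graph Learning and Graph Convolutional Networks for
    Transcriptomic Toxicity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-induced liver injury (DILI) from landmark-gene
    transcriptomic profiles with a graph convolutional classifier whose
    gene-gene graph is learned rather than fixed. A biological graph-learning
    (BioGL) layer combines a STRING-derived protein-protein interaction prior,
    cross-sample gene expression vectors, and GO-enrichment-derived gene
    frequencies into a row-stochastic learned graph that feeds two graph
    convolutional layers and a fully connected classification head. Includes
    MODZ consensus collapsing of biological replicates for scoring new
    compounds, stratified (optionally drug-grouped) cross-validation with the
    usual classification metrics, a synthetic-data generator with planted
    graph-modulated signal for end-to-end testing, and a command-line
    interface over the whole workflow.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
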
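Package: BNIscreen
Title: Discovery of Biological Nitrification Inhibitors from Culture Assays
    and Graph-Attention Activity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for screening biological nitrification
    inhibitors (BNIs). One arm quantifies inhibition of ammonia-oxidizing
    archaea and bacteria from nitrite time series: the ammonia oxidation
    inhibition percentage (AOI%) with pre-treatment baseline subtraction,
    nonparametric group comparisons (Kruskal-Wallis with Dunn/Bonferroni
    post hoc, Wilcoxon), and Euclidean-distance hierarchical clustering of
    compound-by-strain inhibition profiles. The other arm predicts
    inhibitory activity from structure: SMILES canonicalization, tautomer
    enumeration under nine named transformation classes used for data
    augmentation, tautomer-group-aware train/validation/test splitting that
    prevents leakage, a graph-attention network classifier with multi-head
    self-attention, dual global pooling and an optional lipophilicity
    pretraining stage, and model explanation through corrected attention
    weights and Shapley substructure attribution. A synthetic-data module
    generates culture time series and structure-activity libraries with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    ape,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
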
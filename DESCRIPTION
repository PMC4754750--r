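Package: herbtargets
Title: Similarity-Based Compound-Target Prediction and Network
    Pharmacology for Herbal Formulas
Version: 0.1.0
Authors@R:
    person("herbtargets", "developers", email = "devel@herbtargets.org",
           role = c("aut", "cre"))
Description: Predicts protein targets of small-molecule compounds by
    combining multiple drug-drug and protein-protein similarity measures
    into max-similarity-product features, scoring candidate pairs with
    per-feature likelihood ratios (max-LR rule) after minimum-redundancy
    maximum-relevance feature selection.  Includes leave-one-interaction-out
    and leave-one-drug-out cross-validation with ROC/AUC, hypergeometric
    enrichment of predicted target sets against pathway/GO/disease gene-set
    collections with Benjamini-Hochberg correction, assembly and export of
    ingredient-target-pathway/disease association networks, multi-cluster
    target-set comparison, a synthetic-universe generator with planted
    signal for download-free testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
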
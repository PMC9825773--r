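Package: adrnet
Title: Predicting Adverse-Drug-Reaction-Related Proteins by Heterogeneous
    Network Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds an integrated directed network of drugs, proteins and
    fictitious single-target compounds (STCs) from STRING-style
    protein-protein links, STITCH-style chemical-protein links and
    SIDER-style drug-ADR relations; embeds it with second-order biased
    random walks and skip-gram training (node2vec); trains one
    L2-regularized logistic classifier per adverse drug reaction (ADR)
    on the drug embeddings (binary relevance); and reads each protein's
    ADR-relation score off the embedding of its single-target compound.
    Includes the evaluation suite (per-pair confusion counts, positive
    predictive value, value-added PPV, positive likelihood ratio, top-k
    averaging with support filters, benchmark rank recovery, balanced
    negative-sampling evaluation, similarity correlations) and a
    synthetic stochastic-block-model world generator with planted
    ADR-causal protein modules so every stage is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
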
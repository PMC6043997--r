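Package: netprio
Title: Disease-Gene Prioritization from Overlapping Modules of Expression-Filtered Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for predicting novel disease genes from
    RNA-seq counts, a scored protein-protein interaction network and a list of
    known disease genes. Differentially expressed genes are called with a
    negative-binomial conditional exact test after trimmed-mean-of-M-values
    normalization, genes are categorized (known-and-differential, only
    differential, other) to filter interactions by per-pair-type confidence
    thresholds, the resulting network is decomposed into overlapping dense
    modules with the DPClusO greedy clustering algorithm, modules are scored
    for enrichment of known disease genes by one-sided Fisher tests, and each
    gene receives a significance score (-log of its best module p-value) used
    for ROC-based density selection and prediction of novel candidates. A
    fully synthetic data generator with planted differential expression,
    planted network modules and hidden disease genes supports end-to-end
    recovery testing without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
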
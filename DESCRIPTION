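Package: focaltc
Title: Time-Course Expression Analysis of Focal High-Dose Lung Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for time-course microarray expression data
    from focally irradiated lung tissue: probe filtering against local
    background, quantile normalization, log2 expression ratios versus a
    pooled control, short time-series model-profile clustering with
    permutation significance, over-representation analysis with
    Benjamini-Hochberg correction, semantic-similarity-based reduction of
    redundant ontology terms, topology-based signaling pathway impact
    analysis (over-representation and perturbation evidence combined),
    sign-weighted pathway activity indices with a permutation null, and
    Markov clustering of co-expression-filtered functional interaction
    networks. A synthetic-data generator with planted temporal patterns,
    enriched gene sets, perturbed pathway topologies, and network modules
    makes every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    fgsea,
    igraph,
    jsonlite,
    limma,
    methods,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
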
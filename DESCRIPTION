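Package: mosaicbridge
Title: Mosaic Single-Cell Data Integration via Regression Bridges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Embeds two or more single-cell feature matrices with only
    partially overlapping (or pairwise disjoint) feature panels into a
    common low-dimensional space. Datasets are organised in a feature-overlap
    graph (the mosaic data topology); every dataset is projected onto each
    reference dataset's PCA or LDA coordinates either directly or by chaining
    least-squares regression bridges along weighted shortest paths through
    the graph, so that datasets sharing no features can still be co-embedded
    through intermediate bridge datasets. Includes k-nearest-neighbour label
    transfer and feature imputation on the joint embedding, quantitative
    evaluation metrics for matched multi-omic embeddings, spatial
    neighbourhood feature extraction, a per-cell local enrichment test based
    on binomial regression with likelihood-ratio testing, and a synthetic
    mosaic data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
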
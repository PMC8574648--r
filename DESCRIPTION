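Package: biclusteval
Title: Simulation and Evaluation Toolkit for Sparse Biclustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking biclustering algorithms on gene expression
    data. Provides a generative simulator for expression matrices with
    implanted, possibly overlapping biclusters under negative-binomial,
    Gaussian, noiseless and shift-scale value models, including multi-tissue
    tensor designs and a synthetic knockout-experiment fixture; a suite of
    evaluation metrics (clustering error via optimal bicluster matching,
    normalised reconstruction error, mean bicluster redundancy, Jaccard
    recovery and relevance, trait F1 scores, run-to-run similarity); pathway
    enrichment scoring with Benjamini-Yekutieli correction and a
    knockout-linked biclustering score; and a thresholding post-processor
    that converts dense loading matrices into sparse bicluster memberships.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
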
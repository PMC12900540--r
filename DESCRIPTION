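Package: stransfer
Title: Transfer Learning for Spatial Transcriptomics Domain Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates spatial domains on an unlabeled spatial transcriptomics
    slice by transferring knowledge from an annotated neighbouring slice.
    A dual-graph variational graph-convolutional encoder combines a k-nearest
    neighbour spatial graph (local structure) with a positive pointwise mutual
    information graph derived from truncated random walks (global structure),
    fuses the two branches with per-spot attention weights, and feeds the fused
    embedding to a residual-block cluster classifier trained on the source
    slice. An adversarial domain-adaptation phase aligns target embeddings with
    the source so the classifier's labels carry over. Includes a synthetic
    slice-pair generator with controllable batch effects, evaluation metrics
    (adjusted Rand index, clustering accuracy, confusion reports), and CSV
    import/export of slices, predictions and embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
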
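Package: svgae
Title: Signed Variational Graph Auto-Encoders for Protein-Protein
    Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns low-dimensional protein embeddings from a
    protein-protein interaction (PPI) graph together with conjoint-triad
    sequence features, using a signed variational graph auto-encoder: a
    two-layer graph-convolutional variational encoder over a signed
    adjacency matrix (+1 observed interactions, -1 high-confidence
    non-interactions, 0 uncertain), an inner-product decoder, and a
    reconstruction loss restricted to the high-confidence cells.  A small
    feedforward classifier maps concatenated embedding pairs to an
    interaction probability.  Includes the subcellular-localization-based
    negative-sampling filters, stratified repeated-split evaluation with
    the standard five classification metrics, a coverage-sparsification
    robustness sweep, a signed-versus-unsigned ablation, and a synthetic
    attributed-graph generator with planted interaction structure so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
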
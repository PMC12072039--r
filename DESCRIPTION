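Package: gtgo
Title: Protein Function Prediction from PPI Networks and Protein Language
    Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-label Gene Ontology term prediction from weighted
    protein-protein interaction networks and precomputed protein language
    model embeddings. The PPI branch is a dual-branch graph transformer: a
    two-layer edge-weighted residual graph convolutional network captures
    local neighbourhood structure while a softmax-free linear-attention
    encoder captures global network context without materialising the full
    attention matrix. PPI and sequence embeddings are fused by concatenation
    and scored by a sigmoid GO-term classifier trained with binary
    cross-entropy, Adam, and early stopping. Includes a seeded synthetic
    benchmark generator (planted-partition networks with module-correlated
    features, labels and embeddings), CAFA-style protein-centric evaluation
    (Fmax and micro-AUPR), and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
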
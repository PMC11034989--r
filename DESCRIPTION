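Package: gpgcn
Title: Gapped Pattern Graph Convolutional Networks for DNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes DNA sequences as gapped pattern graphs (k-mer vertices,
    gap-resolved k-mer-pair edges), embeds them with a two-step graph
    convolutional network followed by a small convolutional head, and trains
    task classifiers on the embeddings. Includes class-imbalance-aware
    training with Adam, hyperparameter grid search, occlusion-based
    contribution scores for gapped patterns and IUPAC motifs with randomized
    baselines, and a deterministic synthetic-sequence simulator with planted
    gapped-pattern signatures and SNP/indel noise for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
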
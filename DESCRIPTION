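Package: molfuse
Title: Multi-View Molecular Representations with Gated Late Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Featurizes small molecules as three complementary views -- a
    token-level molecular graph with Laplacian positional encoding, a
    rendered 2D depiction, and a regex-tokenized SMILES sequence -- and
    combines per-view embeddings through an interpretable gated late-fusion
    aggregator whose softmax gate weights expose each view's contribution.
    Includes self-supervised target generators (token masking, graph feature
    masking, edge corruption, and per-node Betti-number topology targets),
    desk-scale per-view encoders, Murcko-scaffold-aware dataset splitting,
    fine-tuning with per-subnetwork learning rates, a drug-target
    interaction head over externally supplied protein embeddings, and a
    deterministic synthetic molecule generator so the full pipeline runs
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
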
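Package: chemformer
Title: Multi-Scale Graph Transformer Models for Molecular Property Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts molecular properties from SMILES with a multi-scale
    neural architecture that fuses an atom graph, a bond (line) graph, a
    3D-equivariant encoder, and classical molecular fingerprint panels.
    Graph channels are processed by a graph-convolution stack followed by
    transformer encoder blocks with an equivariant coordinate update and a
    learned graph-representation (CLS) node; fingerprint panels feed a
    feed-forward channel.  Includes dataset reading and cleaning, seeded 3D
    conformer embedding, eight fingerprint families, scaffold and random
    splits, multi-seed benchmarking harnesses (fingerprint selection,
    architecture ablations, label-noise robustness), and attention-based
    per-atom/per-bond interpretability, plus a deterministic synthetic
    molecule and label generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (used via ChemmineOB); Python 3 with RDKit
    on the PATH for seeded 3D conformer embedding.
Config/testthat/edition: 3
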
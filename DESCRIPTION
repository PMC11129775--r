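Package: tandemol
Title: Tandem Masked Self-Supervised Pre-Training of SMILES and Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint self-supervised pre-training on two molecular modalities,
    SMILES strings and molecular graphs, through a unified Transformer-style
    fusion backbone trained by masked reconstruction. The package establishes
    an explicit atom-index alignment between SMILES atom tokens and graph
    nodes and uses it to draw coordinated, non-overlapping mask sets in the
    two modalities, so that reconstructing a masked atom in one modality must
    rely on the other modality's unmasked view of it. Includes a lossless
    SMILES tokenizer and corpus-driven vocabulary builder, an atom-order
    preserving SMILES-to-graph featurizer, a communicative node-edge
    message-passing graph encoder, reconstruction objectives (masked token
    cross-entropy and scaled cosine error), a reproducible pre-training loop,
    Bemis-Murcko scaffold splitting with a downstream fine-tuning protocol
    for property prediction, and a deterministic synthetic-molecule generator
    for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    pROC
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
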
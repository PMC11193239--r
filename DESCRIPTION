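Package: smilesgen
Title: Conditional SMILES Generation with a Decoder-Only Transformer and
    Stochastic Context Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A decoder-only, Llama-2-style generative language model for
    molecules in SMILES notation, conditioned on any subset of three numeric
    properties (Crippen logP, synthetic accessibility score, scaled molecular
    weight) and an optional core-structure token sequence. Implements the
    character-level-except-brackets SMILES tokenizer, corpus canonicalization
    and filtering, rotary positional embeddings, RMSNorm, SwiGLU feed-forward
    blocks, stochastic context learning (random per-batch condition deletion)
    with a SMILES-only cross-entropy loss, temperature sampling, and the
    standard de novo generation metrics (validity, uniqueness, novelty, mean
    absolute deviation, bond-order-relaxed substructure match). A deterministic
    toy chemical-space generator makes the whole pipeline testable at desk
    scale. Cheminformatics primitives are delegated to the system RDKit
    through a batched command-line bridge.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'chem-bridge.R'
    'tokenizer.R'
    'corpus.R'
    'model-core.R'
    'scl.R'
    'train.R'
    'sampler.R'
    'metrics.R'
    'toy-chem.R'
    'checkpoint.R'
    'cli.R'
    'zzz.R'
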
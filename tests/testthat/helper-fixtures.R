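# Shared fixtures for the test suite.

# A small panel of hand-picked SMILES exercising brackets, two-character
# element symbols, aromatic rings, ring-closure digits, branches, charges,
# chirality marks, and multi-component strings.
panel_smiles <- function() {
  c(
    acetic      = "CC(=O)O",
    benzene     = "c1ccccc1",
    toluene     = "Cc1ccccc1",
    pyridine    = "c1ccncc1",
    chloroform  = "C(Cl)(Cl)Cl",
    bromoethane = "CCBr",
    nitrile     = "CC#N",
    alkene      = "C=CC",
    alanine     = "C[C@@H](N)C(=O)O",
    ammonium    = "C[NH3+].[Cl-]",
    naphthalene = "c1ccc2ccccc2c1",
    cyclohexane = "C1CCCCC1",
    thiophene   = "c1ccsc1",
    isotope     = "[13C]O",
    sulfate     = "OS(=O)(=O)O"
  )
}

# A tiny deterministic corpus for model-level tests.
tiny_corpus <- function() {
  c("CC(=O)O", "c1ccccc1", "CCO", "CC#N", "C1CCCCC1", "CCN", "C=CC", "CCOC")
}

small_model <- function(vocabSize, d = 16L, seed = 7L) {
  cfg <- modelConfig(d = d, nHeads = 2L, nLayersSmiles = 1L, nLayersGraph = 1L,
                     nLayersBackbone = 1L, nLayersGraphDecoder = 1L,
                     maxSeqLen = 64L, vocabSize = vocabSize)
  initModel(cfg, seed = seed)
}
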
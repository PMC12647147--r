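# Shared fixtures, memoized so expensive steps (conformer embedding runs a
# python subprocess) happen once per test session.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- force(expr)
  .fx_cache[[key]]
}

# a small embedded molecule set used across featurization/model tests
fx_mols <- function() {
  fx_memo("mols", {
    smiles <- c("c1ccccc1", "CCO", "C", "CC(=O)Nc1ccc(O)cc1", "CC(C)CC#N",
                "c1ccncc1", "OC(=O)c1ccccc1", "CCSC", "C1CCCCC1", "ClCCBr")
    mols <- chemformer:::.embed_smiles(canonical_smiles(smiles), seed = 1)
    names(mols) <- smiles
    mols
  })
}

fx_mol <- function(smiles) fx_mols()[[smiles]]

# 50 generated molecules with embedded conformers, for property tests
fx_pool <- function() {
  fx_memo("pool", {
    smi <- generate_molecules(50, seed = 101)
    chemformer:::.embed_smiles(smi, seed = 1)
  })
}

# a small embedded classification dataset shared by training tests
fx_clf_data <- function() {
  fx_memo("clf", {
    d <- make_fixture_dataset(60, seed = 31)
    embed_conformers(d, seed = 1)
  })
}

# tiny config + params for model tests
fx_small_config <- function(variant = "Full", ...) {
  model_config(variant, hidden_dim = 8L, gcn_layers = 2L,
               encoder_blocks = 2L, attention_heads = 2L, dropout = 0, ...)
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(unlist(x))))
}
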
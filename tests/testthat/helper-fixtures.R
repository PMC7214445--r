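# Shared fixtures. Heavy objects (synthetic corpora, trained models) are
# built once per test session and reused across files.

.fx <- new.env(parent = emptyenv())

# memoise a fixture by name
fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# A tiny labeled cleavage table over a handful of molecules, enough to build
# vocabularies and models without training.
tiny_bde_table <- function() {
  fixture("tiny_tab", function() {
    mols <- c("C", "CC", "CCO", "CC(N)=O", "CCC", "CO")
    tab <- gen_cleavage_table(mols, oracle_params(noise_sigma = 0))
    tab
  })
}

tiny_dataset <- function() {
  fixture("tiny_ds", function() prepare_bde_dataset(tiny_bde_table()))
}

tiny_vocab <- function() {
  fixture("tiny_vocab", function()
    vocab_build(lapply(tiny_dataset(), `[[`, "graph")))
}

# An untrained model over the tiny vocabulary (small width so forward passes
# are instant).
tiny_model <- function(seed = 7L) {
  fixture("tiny_model", function() {
    cfg <- model_config(state_dim = 16L, n_blocks = 3L, epochs = 1L,
                        batch_size = 4L, seed = seed)
    model_init(cfg, tiny_vocab(), class_mean_bdes(tiny_bde_table()))
  })
}

# Labels of a prepared dataset as a data.frame (for class means).
labels_of <- function(ds) {
  do.call(rbind, lapply(ds, function(e) {
    bi <- as.integer(names(e$labels))
    data.frame(bond_type = e$graph$bond_types[bi],
               bde_kcal_mol = as.numeric(e$labels))
  }))
}

# Pack a prepared dataset against a vocabulary (reaches into package
# internals on purpose: several tests compare the compiled kernels with the
# reference R implementation).
pack_dataset <- function(ds, vocab) {
  entries <- lapply(ds, function(e)
    bdegnn:::.mol_entry(encode_graph(vocab, e$graph), e$labels))
  bdegnn:::.pack(entries)
}
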
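# Shared fixtures, built once per test run and memoized. The tiny trained
# models take ~1 minute each to fit; every test that needs a trained state
# reuses them.

.mf_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.mf_cache[[key]])) .mf_cache[[key]] <- force(expr)
  .mf_cache[[key]]
}

toy_ontology <- function() memo("onto", make_toy_ontology())

# 50-molecule corpus with injective (descriptors, scaffold) contexts: the
# substrate for the memorization / adherence experiments
recon_raw <- function() memo("recon_raw",
  make_toy_corpus(toy_corpus_spec(n_molecules = 50, seed = 11,
                                  unique_profiles = TRUE)))

recon_corpus <- function() memo("recon_corpus",
  build_training_corpus(recon_raw()$smiles, toy_ontology(), mode = "hybrid"))

tiny_config <- function() model_config(n_layers = 2, n_heads = 4, d_model = 64,
                                       d_ffn = 128, dropout = 0,
                                       max_positions = 80)

# overfit tiny model: reconstruction experiment configuration (augmentation
# off, target-span loss, no early stop — the conditional-reconstruction
# measurement needs the pure memorization objective)
overfit_model <- function() memo("overfit", {
  tcfg <- train_config(max_epochs = 200, batch_size = 16, warmup_steps = 200,
                       augment_p = 0, patience = Inf, loss_span = "target",
                       seed = 5)
  pretrain(recon_corpus(), tiny_config(), tcfg)
})

# broader unconditional corpus (alert-bearing molecules a minority) and a
# model trained on it with the full default protocol (augmentation on), used
# for the temperature-decomposition experiment
uncond_raw <- function() memo("uncond_raw",
  make_toy_corpus(toy_corpus_spec(n_molecules = 120, seed = 23)))

uncond_corpus <- function() memo("uncond_corpus",
  build_training_corpus(uncond_raw()$smiles, toy_ontology(),
                        mode = "unconditional"))

uncond_model <- function() memo("uncond_model", {
  tcfg <- train_config(max_epochs = 80, batch_size = 16, warmup_steps = 200,
                       augment_p = 0.1, patience = Inf, seed = 7)
  pretrain(uncond_corpus(), tiny_config(), tcfg)
})
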
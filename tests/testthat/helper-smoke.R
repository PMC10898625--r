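# Shared fixtures built in code.  The desk-scale smoke model (3 synthetic
# sites, 64x64 canvas, 50 training anatomies per site, 10 paired test
# anatomies, 1500 training steps) is trained once per test session and
# reused by every test that needs a trained model.

.smoke_cache <- new.env(parent = emptyenv())

smoke_conditions <- function() {
  list(n_sites = 3L, n_train = 50L, n_paired = 10L, spec_seed = 7L,
       data_seed = 11L, train_seed = 5L, steps = 1500L, canvas = 64L,
       width = 8L, downsampling = 2L, lr = 1e-3)
}

get_smoke_dataset <- function() {
  if (is.null(.smoke_cache$dataset)) {
    sc <- smoke_conditions()
    specs <- make_site_specs(sc$n_sites, seed = sc$spec_seed)
    .smoke_cache$dataset <- make_dataset(specs, sc$n_train, sc$n_paired,
                                         seed = sc$data_seed,
                                         shape = c(sc$canvas, sc$canvas))
  }
  .smoke_cache$dataset
}

get_smoke_model <- function() {
  if (is.null(.smoke_cache$model)) {
    sc <- smoke_conditions()
    ds <- get_smoke_dataset()
    cfg <- train_config(total_steps = sc$steps, batch_size = 4L,
                        learning_rate = sc$lr, seed = sc$train_seed)
    mcfg <- model_config(n_sites = sc$n_sites, canvas = sc$canvas,
                         width = sc$width, downsampling = sc$downsampling)
    .smoke_cache$model <- harmonize_fit(ds, cfg, mcfg)
  }
  .smoke_cache$model
}

# A small untrained bundle for contract tests.
tiny_bundle <- function(n_sites = 3L, canvas = 32L, width = 4L, seed = 3L) {
  build_models(model_config(n_sites = n_sites, canvas = canvas, width = width),
               seed = seed)
}

# Random in-range input batch for a bundle.
tiny_input <- function(bundle, n = 1L, seed = 1L) {
  cv <- bundle$config$canvas
  withr::with_seed(seed, array(tanh(rnorm(cv * cv * 3 * n)), c(cv, cv, 3, n)))
}

# Bitwise snapshot of all parameter values of a bundle.
param_snapshot <- function(bundle) {
  sh <- asNamespace("styleharm")
  lapply(sh$collect_params(bundle), function(p) p$value)
}
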
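# Shared fixtures, built once per test run and cached in this environment.
.fix <- new.env(parent = emptyenv())

# small cohort + template at 16^3 used across module tests
fix_dataset <- function(dataset_id = 1, n = 16, seed = 1) {
  key <- sprintf("ds_%d_%d_%d", dataset_id, n, seed)
  if (is.null(.fix[[key]])) {
    cfg <- generation_config(dataset_id, template_shape = c(16, 16, 16),
                             shared_radius_range = c(0.24, 0.32),
                             specific_delta_range = c(0.04, 0.08))
    .fix[[key]] <- generate_dataset(dataset_id, n, cfg, seed = seed)
  }
  .fix[[key]]
}

tiny_spec <- function(kind = "cvae", side = 8, filters = c(2, 3)) {
  model_spec(kind, input_shape = rep(side, 3), conv_filters = filters,
             batch_size = 8)
}

# untrained model with random weights (exact architectural invariants
# must hold for any weights)
random_model <- function(kind = "cvae", side = 8, seed = 99, filters = c(2, 3)) {
  spec <- tiny_spec(kind, side, filters)
  structure(list(weights = with_seed(seed, neurocvae:::init_weights(spec)),
                 spec = spec, seed = seed, epochs = 0L, adam = NULL,
                 step = 0L, history = data.frame(), flagged = FALSE),
            class = "cvae")
}

with_seed <- neurocvae:::with_seed

# brief trained model on the 16-subject fixture, cached
fix_model <- function(kind = "cvae", epochs = 8) {
  key <- paste0("model_", kind, "_", epochs)
  if (is.null(.fix[[key]])) {
    ds <- fix_dataset()
    spec <- model_spec(kind, input_shape = c(16, 16, 16),
                       conv_filters = c(4, 8), batch_size = 8)
    .fix[[key]] <- cvae(ds, spec = spec, epochs = epochs, seed = 5)
  }
  .fix[[key]]
}
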
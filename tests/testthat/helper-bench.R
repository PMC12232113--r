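# Reduced-scale trained runs shared by the acceptance ordinal tests.
# One ensemble per (kind, dataset, n), trained once per test session.
.bench <- new.env(parent = emptyenv())

bench_profile <- list(name = "test", shape = c(16, 16, 16), n = 160,
                      pool_size = 4, keep = 3, stage1_epochs = 4,
                      total_epochs = 60, conv_filters = c(8, 16),
                      latent_dim = 2, batch_size = 20, learning_rate = 1e-3)

bench_dataset <- function(dataset_id, n = bench_profile$n, stream = 100) {
  key <- sprintf("ds_%d_%d_%d", dataset_id, n, stream)
  if (is.null(.bench[[key]]))
    .bench[[key]] <- neurocvae:::profile_dataset(
      bench_profile, dataset_id,
      seed = neurocvae:::derive_seed(20260901, dataset_id * 1000 + stream),
      n = n)
  .bench[[key]]
}

bench_ensemble <- function(kind, dataset_id, n = bench_profile$n,
                           stream = 100, total_epochs = NULL) {
  key <- sprintf("ens_%s_%d_%d_%d", kind, dataset_id, n, stream)
  if (is.null(.bench[[key]])) {
    data <- bench_dataset(dataset_id, n, stream)
    prof <- bench_profile
    if (!is.null(total_epochs)) prof$total_epochs <- total_epochs
    .bench[[key]] <- neurocvae:::profile_ensemble(
      prof, data, kind,
      master_seed = neurocvae:::derive_seed(315, dataset_id * 7 + n))
  }
  .bench[[key]]
}

bench_ari <- function(kind, dataset_id, n = bench_profile$n) {
  ds <- bench_dataset(dataset_id, n)
  ens <- bench_ensemble(kind, dataset_id, n)
  pat <- ds$truth$group != "control"
  space <- if (kind == "vae") "latent" else "specific"
  fm <- ensemble_feature_matrix(ens, ds$volumes[, pat], space)
  cluster_and_score(fm, ds$config$n_subtypes, ds$truth$subtype[pat],
                    seed = 77)
}
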
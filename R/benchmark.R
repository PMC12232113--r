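# End-to-end experiment runner and scale profiles.

#' Scale profiles
#'
#' Bundled problem sizes: `"desk"` runs the full pipeline on one CPU in
#' minutes (16^3 volumes, 240 subjects, pool 8 -> keep 5 models, epochs
#' 5 -> 75, filters 8/16); `"full"` is the benchmark's full-scale
#' configuration (64^3, 1000 subjects, pool 50 -> keep 20, epochs
#' 10 -> 100, filters 32/64) and needs hours of compute.
#'
#' @param name `"desk"` or `"full"`.
#' @return Named list of sizes used by [run_benchmark()].
#' @export
scale_profile <- function(name = c("desk", "full")) {
  name <- match.arg(name)
  if (name == "desk")
    list(name = "desk", shape = c(16, 16, 16), n = 240,
         pool_size = 8, keep = 5, stage1_epochs = 5, total_epochs = 75,
         conv_filters = c(8, 16), latent_dim = 2, batch_size = 25,
         learning_rate = 1e-3)
  else
    list(name = "full", shape = c(64, 64, 64), n = 1000,
         pool_size = 50, keep = 20, stage1_epochs = 10, total_epochs = 100,
         conv_filters = c(32, 64), latent_dim = 2, batch_size = 32,
         learning_rate = 1e-3)
}

profile_spec <- function(profile, kind) {
  model_spec(kind, input_shape = profile$shape,
             latent_dim = profile$latent_dim,
             conv_filters = profile$conv_filters,
             learning_rate = profile$learning_rate,
             batch_size = profile$batch_size)
}

profile_dataset <- function(profile, dataset_id, seed, n = NULL) {
  n <- n %||% profile$n
  cfg <- generation_config(dataset_id, n_controls = n / 2, n_patients = n / 2,
                           template_shape = profile$shape)
  generate_dataset(dataset_id, n, cfg, seed = seed)
}

profile_ensemble <- function(profile, data, kind, master_seed) {
  cvae_ensemble(data, profile_spec(profile, kind),
                pool_size = profile$pool_size, keep = profile$keep,
                stage1_epochs = profile$stage1_epochs,
                total_epochs = profile$total_epochs,
                master_seed = master_seed)
}

#' Run a benchmark experiment grid
#'
#' Executes generate -> train -> analyze for the requested dataset design
#' and returns a machine-readable report: RSA correlations of the CVAE
#' shared/specific spaces and the baseline VAE against both ground truths,
#' clustering ARIs and prototype correlations (designs 2-4), held-out
#' generalization and the PCA baseline, and comorbidity locus contrasts
#' (design 5). Every random draw derives from `master_seed`.
#'
#' @param dataset_id design 1-5.
#' @param profile a [scale_profile()].
#' @param master_seed integer seed for the whole run.
#' @param experiments subset of `c("rsa", "subtype", "generalization",
#'   "pca", "comorbid")`; defaults to all that apply to the design.
#' @return Named list report (class `benchmark_report`).
#' @export
run_benchmark <- function(dataset_id = 1, profile = scale_profile("desk"),
                          master_seed = 1, experiments = NULL) {
  if (is.null(experiments)) {
    experiments <- c("rsa", "generalization", "pca")
    if (dataset_id %in% 2:4) experiments <- c(experiments, "subtype")
    if (dataset_id == 5) experiments <- c("rsa", "comorbid")
  }
  report <- list(dataset_id = dataset_id, profile = profile$name,
                 master_seed = master_seed, n = profile$n,
                 shape = profile$shape)
  t0 <- proc.time()[3]
  data <- profile_dataset(profile, dataset_id,
                          seed = derive_seed(master_seed, 100))
  kind <- if (dataset_id == 5) "comorbid_cvae" else "cvae"
  ens <- profile_ensemble(profile, data, kind, derive_seed(master_seed, 1))
  report$timing_generate_train <- proc.time()[3] - t0

  if ("rsa" %in% experiments) {
    sp <- if (dataset_id == 5) "d1" else "specific"
    report$tau_shared <- ensemble_rsa(ens, data, "shared", "shared")$tau
    report$tau_specific <- ensemble_rsa(ens, data, sp, "specific")$tau
    report$tau_shared_vs_specific <-
      ensemble_rsa(ens, data, "shared", "specific")$tau
    vae <- profile_ensemble(profile, data, "vae", derive_seed(master_seed, 2))
    report$tau_vae_specific <- ensemble_rsa(vae, data, "latent", "specific")$tau
    report$tau_vae_shared <- ensemble_rsa(vae, data, "latent", "shared")$tau
    report$variance_explained <- variance_explained(ens, data)
  }
  if ("subtype" %in% experiments) {
    pat <- data$truth$group != "control"
    fm <- ensemble_feature_matrix(ens, data$volumes[, pat], "specific")
    cl <- cluster_and_score(fm, data$config$n_subtypes,
                            data$truth$subtype[pat],
                            seed = derive_seed(master_seed, 3))
    report$ari_cvae <- cl$ari
    report$prototype_r_cvae <- cvae_prototypes(ens, data, cl)$mean_r
    vae <- profile_ensemble(profile, data, "vae", derive_seed(master_seed, 2))
    fmv <- ensemble_feature_matrix(vae, data$volumes[, pat], "latent")
    clv <- cluster_and_score(fmv, data$config$n_subtypes,
                             data$truth$subtype[pat],
                             seed = derive_seed(master_seed, 3))
    report$ari_vae <- clv$ari
    report$prototype_r_vae <- vae_prototypes(data, clv)$mean_r
  }
  if ("generalization" %in% experiments) {
    heldout <- profile_dataset(profile, dataset_id,
                               seed = derive_seed(master_seed, 200))
    sp <- if (dataset_id == 5) "d1" else "specific"
    report$tau_specific_heldout <-
      ensemble_rsa(ens, heldout, sp, "specific")$tau
    report$tau_shared_heldout <- ensemble_rsa(ens, heldout, "shared", "shared")$tau
    if ("pca" %in% experiments) {
      pb <- pca_baseline(data, heldout)
      report$pca_components <- pb$n_components
      report$pca_tau_train <- pb$tau_train
      report$pca_tau_transfer <- pb$tau_transfer
    }
  }
  if ("comorbid" %in% experiments && dataset_id == 5) {
    report <- c(report, comorbid_contrast(ens, data))
  }
  report$timing_total <- proc.time()[3] - t0
  structure(report, class = c("benchmark_report", "list"))
}

# mean |map| inside each disorder's unique locus for d1/d2 maps of
# comorbid subjects, using the reference model
comorbid_contrast <- function(ens, data) {
  model <- reference_model(ens)
  comorbid <- data$truth$group == "disorder1+2"
  X <- data$volumes[, comorbid, drop = FALSE]
  m1 <- rowMeans(abs(comorbid_maps(model, X, "d1")))
  m2 <- rowMeans(abs(comorbid_maps(model, X, "d2")))
  mask1 <- locus_mask(data$config, 1)
  mask2 <- locus_mask(data$config, 2)
  list(d1_map_in_locus1 = mean(m1[mask1]), d1_map_in_locus2 = mean(m1[mask2]),
       d2_map_in_locus1 = mean(m2[mask1]), d2_map_in_locus2 = mean(m2[mask2]))
}

#' Voxel mask of a subtype's unique locus support
#'
#' @param config a [generation_config()].
#' @param subtype subtype / disorder index.
#' @return Logical vector over voxels.
#' @export
locus_mask <- function(config, subtype) {
  as.numeric(ground_truth_subtype_map(config, subtype)) > 0
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report (dataset", x$dataset_id, ",", x$profile, "profile)\n")
  for (k in setdiff(names(x), c("dataset_id", "profile", "shape")))
    if (is.numeric(x[[k]]) && length(x[[k]]) == 1)
      cat(sprintf("  %-24s %s\n", k, signif(x[[k]], 4)))
  invisible(x)
}

#' Write a benchmark report
#'
#' Serializes the report as YAML next to a TSV of its scalar metrics.
#'
#' @param report a [run_benchmark()] report.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(report), file.path(dir, "report.yaml"))
  scal <- Filter(function(v) is.numeric(v) && length(v) == 1, unclass(report))
  write.table(data.frame(metric = names(scal), value = unlist(scal)),
              file.path(dir, "report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Small deterministic test fixture
#'
#' Sixteen subjects (8 controls, 8 patients) on a 32^3 grid with exaggerated
#' effect magnitudes; generates in seconds and is used throughout the unit
#' tests.
#'
#' @param seed integer seed.
#' @param dataset_id design to draw from.
#' @param shape grid side (cubic).
#' @export
fixture_dataset <- function(seed = 1, dataset_id = 1, shape = c(32, 32, 32)) {
  cfg <- generation_config(dataset_id, n_controls = 8, n_patients = 8,
                           template_shape = shape,
                           shared_radius_range = c(0.24, 0.32),
                           specific_delta_range = c(0.04, 0.08))
  n <- if (dataset_id == 5) 12 else 16
  generate_dataset(dataset_id, n, cfg, seed = seed)
}
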
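# Two-stage hierarchical ensemble training: a pool of candidates is trained
# briefly, the k candidates with the lowest reconstruction loss are kept and
# trained to completion. Selection guards against bad initializations and
# posterior collapse; averaging analyses across the survivors stabilizes
# the downstream metrics.

#' Stage 1: train a candidate pool
#'
#' Trains `pool_size` models independently for a few epochs, each with a
#' distinct seed derived from `master_seed` (weight initialization and data
#' shuffling), and tags each with its end-of-stage reconstruction (MSE) loss
#' on the training set. Candidates with non-finite loss are flagged and
#' excluded from selection.
#'
#' @param spec a [model_spec()].
#' @param data a `synthetic_dataset`.
#' @param pool_size number of candidates.
#' @param epochs stage-1 epochs.
#' @param master_seed integer; the whole two-stage procedure is
#'   deterministic given `(master_seed, spec, data)`.
#' @return List of candidates, each `list(model, seed_index, loss, flagged)`.
#' @export
train_stage1 <- function(spec, data, pool_size = 10, epochs = 5,
                         master_seed = 1) {
  if (pool_size < 1) stop("pool_size must be >= 1")
  lapply(seq_len(pool_size), function(i) {
    m <- cvae(data, spec = spec, epochs = epochs,
              seed = derive_seed(master_seed, i))
    loss <- if (m$flagged) Inf else evaluate_loss(m, data)$mse
    if (!is.finite(loss)) m$flagged <- TRUE
    list(model = m, seed_index = i, loss = loss, flagged = m$flagged)
  })
}

#' Stage 1 -> 2 selection
#'
#' Keeps the `k` unflagged candidates with the lowest stage-1 reconstruction
#' loss; ties are broken in favor of the lower seed index.
#'
#' @param pool output of [train_stage1()].
#' @param k number of models to keep.
#' @return The selected candidates in selection order.
#' @export
select_top <- function(pool, k) {
  ok <- Filter(function(c) !c$flagged, pool)
  if (length(ok) < k)
    stop("only ", length(ok), " unflagged candidates; need ", k)
  losses <- vapply(ok, `[[`, 0, "loss")
  idx <- as.numeric(vapply(ok, `[[`, 0, "seed_index"))
  ok[order(losses, idx)[seq_len(k)]]
}

#' Stage 2: train the selected models to completion
#'
#' Each selected model continues training (warm start; fresh models can be
#' requested with `restart = TRUE`) up to `total_epochs`. Models that turn
#' non-finite are kept but flagged.
#'
#' @param selected output of [select_top()].
#' @param data the training data.
#' @param total_epochs cumulative epoch count per model.
#' @param restart retrain from scratch for `total_epochs` instead of
#'   continuing.
#' @return List of candidates with updated models.
#' @export
train_stage2 <- function(selected, data, total_epochs = 30, restart = FALSE) {
  lapply(selected, function(c) {
    m <- c$model
    if (restart) {
      m <- cvae(data, spec = m$spec, epochs = total_epochs, seed = m$seed)
    } else if (total_epochs > m$epochs) {
      m <- train_more(m, data, total_epochs - m$epochs)
    }
    c$model <- m
    c$flagged <- m$flagged
    c$final_loss <- if (m$flagged) Inf else evaluate_loss(m, data)$mse
    c
  })
}

#' Two-stage ensemble fit
#'
#' Convenience wrapper running [train_stage1()], [select_top()] and
#' [train_stage2()].
#'
#' @inheritParams train_stage1
#' @param keep ensemble size after selection.
#' @param stage1_epochs,total_epochs the two training durations.
#' @return An object of class `cvae_ensemble`: `models` (list of fitted
#'   `cvae`), `seeds`, `selection_losses` (all stage-1 losses),
#'   `final_losses`, `flagged`, `spec`, `master_seed`.
#' @export
cvae_ensemble <- function(data, spec, pool_size = 10, keep = 5,
                          stage1_epochs = 5, total_epochs = 30,
                          master_seed = 1) {
  pool <- train_stage1(spec, data, pool_size, stage1_epochs, master_seed)
  sel <- select_top(pool, keep)
  sel <- train_stage2(sel, data, total_epochs)
  structure(list(
    models = lapply(sel, `[[`, "model"),
    seeds = vapply(sel, `[[`, 0L, "seed_index"),
    selection_losses = vapply(pool, `[[`, 0, "loss"),
    final_losses = vapply(sel, `[[`, 0, "final_loss"),
    flagged = vapply(sel, `[[`, TRUE, "flagged"),
    spec = spec, master_seed = master_seed,
    stage1_epochs = stage1_epochs, total_epochs = total_epochs,
    pool_size = pool_size), class = "cvae_ensemble")
}

#' @export
print.cvae_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d %s models (pool %d, epochs %d -> %d)\n",
              length(x$models), x$spec$kind, x$pool_size,
              x$stage1_epochs, x$total_epochs))
  cat(sprintf("  final reconstruction losses: %s\n",
              paste(signif(x$final_losses, 4), collapse = ", ")))
  invisible(x)
}

#' @export
summary.cvae_ensemble <- function(object, ...) {
  print(object)
  cat(sprintf("  stage-1 losses (all %d candidates): %s\n",
              object$pool_size,
              paste(signif(object$selection_losses, 4), collapse = ", ")))
  invisible(object)
}

#' Ensemble latent predictions
#'
#' @param object a `cvae_ensemble`.
#' @param newdata dataset or volume matrix.
#' @param type `"latent"` returns per-model posterior means; `"features"`
#'   returns the concatenated feature matrix of
#'   [ensemble_feature_matrix()].
#' @param space feature space for `type = "features"`.
#' @param ... unused.
#' @export
predict.cvae_ensemble <- function(object, newdata, type = c("latent", "features"),
                                  space = "specific", ...) {
  type <- match.arg(type)
  if (type == "latent")
    return(lapply(object$models, predict, newdata = newdata, type = "latent"))
  ensemble_feature_matrix(object, newdata, space)
}

#' Reference model of an ensemble
#'
#' The member with the lowest final reconstruction loss (used for prototype
#' and counterfactual maps).
#'
#' @param ensemble a `cvae_ensemble`.
#' @export
reference_model <- function(ensemble) {
  ensemble$models[[which.min(ensemble$final_losses)]]
}

#' Reliability of single models versus ensemble averages
#'
#' Repeats the whole two-stage procedure `n_repeats` times with different
#' derived master seeds (the candidate pool is re-drawn each repeat). For
#' each repeat it computes variance explained and the shared / specific RSA
#' correlations, both per individual model and averaged within the ensemble,
#' and reports the across-repeat standard deviation of each, plus the
#' single-model-to-ensemble SD ratios.
#'
#' @param data training data.
#' @param spec a [model_spec()].
#' @param n_repeats number of repeats (>= 2).
#' @param master_seed base seed.
#' @param ... passed to [cvae_ensemble()].
#' @return List with `per_repeat` (data frame of ensemble-averaged metrics),
#'   `sd_individual`, `sd_ensemble`, `sd_ratio` (named vectors over metrics
#'   `var_explained`, `tau_shared`, `tau_specific`).
#' @export
reliability_protocol <- function(data, spec, n_repeats = 5, master_seed = 1,
                                 ...) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  metrics_e <- list(); metrics_i <- list()
  for (r in seq_len(n_repeats)) {
    ens <- cvae_ensemble(data, spec, master_seed = derive_seed(master_seed, r),
                         ...)
    sh_space <- if (spec$kind == "vae") "latent" else "shared"
    sp_space <- if (spec$kind == "vae") "latent" else "specific"
    rs_sh <- ensemble_rsa(ens, data, space = sh_space, ground_truth = "shared")
    rs_sp <- ensemble_rsa(ens, data, space = sp_space, ground_truth = "specific")
    ve_i <- vapply(ens$models, variance_explained, 0, data = data)
    metrics_e[[r]] <- c(var_explained = mean(ve_i), tau_shared = rs_sh$tau,
                        tau_specific = rs_sp$tau)
    metrics_i[[r]] <- rbind(var_explained = ve_i,
                            tau_shared = rs_sh$per_model_taus,
                            tau_specific = rs_sp$per_model_taus)
  }
  per_repeat <- do.call(rbind, metrics_e)
  sd_ensemble <- apply(per_repeat, 2, sd)
  # per-model-slot SD across repeats, averaged over slots
  arr <- simplify2array(metrics_i)            # metric x model x repeat
  sd_individual <- apply(apply(arr, c(1, 2), sd), 1, mean)
  list(per_repeat = as.data.frame(per_repeat),
       sd_individual = sd_individual,
       sd_ensemble = sd_ensemble,
       sd_ratio = sd_individual / sd_ensemble)
}
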
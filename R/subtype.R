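# Subtyping on ensemble latents, ARI scoring, and counterfactual
# (synthetic-twin) difference maps.

#' Concatenated ensemble feature matrix
#'
#' Per-subject latent posterior means of one feature space, concatenated
#' across ensemble members in model order (columns `latent_dim` per model).
#' For the baseline VAE use `space = "latent"`.
#'
#' @param ensemble a `cvae_ensemble`.
#' @param data a `synthetic_dataset`, voxel matrix, or subset thereof.
#' @param space feature space name.
#' @return subjects x (models * latent_dim) matrix.
#' @export
ensemble_feature_matrix <- function(ensemble, data, space = "specific") {
  X <- if (inherits(data, "synthetic_dataset")) data$volumes else data
  blocks <- lapply(ensemble$models, function(m) {
    mu <- encode(m, X)$mu[[space]]
    if (is.null(mu)) stop("model has no feature space '", space, "'")
    t(mu)
  })
  do.call(cbind, blocks)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions via the contingency
#' formula: 1 for identical partitions (up to label permutation), around 0
#' at chance.
#'
#' @param a,b integer label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' K-means subtyping scored against ground truth
#'
#' Seeded K-means with restarts (best within-cluster sum of squares kept),
#' scored by the adjusted Rand index against ground-truth subtype labels.
#'
#' @param features subjects x features matrix (e.g.
#'   [ensemble_feature_matrix()] over patients).
#' @param k number of clusters (set from the ground truth).
#' @param truth_labels ground-truth subtype labels, one per row of
#'   `features`.
#' @param n_restarts random restarts.
#' @param seed RNG seed for the restarts.
#' @return List of class `clustering_result`: `labels`, `k`, `ari`,
#'   `feature_matrix_shape`.
#' @export
cluster_and_score <- function(features, k, truth_labels, n_restarts = 10,
                              seed = 1) {
  features <- as.matrix(features)
  if (k < 2) stop("k must be >= 2")
  if (nrow(features) < k) stop("fewer subjects than clusters")
  km <- with_seed(seed,
                  kmeans(features, centers = k, nstart = n_restarts,
                         iter.max = 50))
  structure(list(labels = unname(km$cluster) - 1L, k = as.integer(k),
                 ari = adjusted_rand_index(km$cluster, truth_labels),
                 feature_matrix_shape = dim(features)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("K-means (k = %d) on %d x %d features: ARI = %.3f\n",
              x$k, x$feature_matrix_shape[1], x$feature_matrix_shape[2],
              x$ari))
  invisible(x)
}

#' Synthetic-twin counterfactual difference maps
#'
#' Each subject is reconstructed twice from its posterior means: once with
#' all of its group's active spaces and once with shared features only (the
#' synthetic twin, a counterfactual matched on disorder-unrelated anatomy).
#' The difference localizes disorder-related anatomy.
#'
#' @param model a fitted contrastive model (`cvae` or `comorbid_cvae`; the
#'   baseline VAE has no shared/specific split).
#' @param data a `synthetic_dataset` or voxel matrix.
#' @param groups group labels when `data` is a bare matrix.
#' @return voxels x subjects matrix of signed differences
#'   (reconstruction minus twin).
#' @export
synthetic_twin <- function(model, data, groups = NULL) {
  if (model$spec$kind == "vae")
    stop("synthetic twins require a contrastive model")
  X <- if (inherits(data, "synthetic_dataset")) data$volumes else data
  if (is.null(groups) && inherits(data, "synthetic_dataset"))
    groups <- data$truth$group
  enc <- encode(model, X)
  full <- decode(model, enc$mu, groups = groups)
  twin <- decode(model, enc$mu, active = "shared")
  full - twin
}

# optimal one-to-one cluster-to-subtype matching maximizing total Pearson r
match_prototypes <- function(proto, gt_maps, mask) {
  k <- length(proto)
  cmat <- matrix(NA_real_, k, length(gt_maps))
  for (i in seq_len(k))
    for (j in seq_along(gt_maps))
      cmat[i, j] <- suppressWarnings(
        stats::cor(proto[[i]][mask], gt_maps[[j]][mask]))
  cmat[!is.finite(cmat)] <- -1
  perms <- all_permutations(seq_len(ncol(cmat)))
  best <- perms[[which.max(vapply(perms, function(p)
    sum(cmat[cbind(seq_len(k), p[seq_len(k)])]), 0))]]
  r <- cmat[cbind(seq_len(k), best[seq_len(k)])]
  list(assignment = best[seq_len(k)], r = r, mean_r = mean(r),
       correlation_matrix = cmat)
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(all_permutations(x[-i]), function(p) c(x[i], p)))
  out
}

#' Cluster prototypes from CVAE synthetic twins
#'
#' For each cluster, the prototype is the voxelwise mean of the absolute
#' synthetic-twin difference maps of its members, computed from a single
#' reference model (the ensemble member with the lowest final loss) or
#' averaged across all members. Prototypes are matched one-to-one to the
#' ground-truth subtype magnitude maps by maximizing the summed within-mask
#' Pearson correlation.
#'
#' @param ensemble a `cvae_ensemble` of contrastive models.
#' @param data the `synthetic_dataset` the clustering was computed on.
#' @param clustering a [cluster_and_score()] result over the patients of
#'   `data`.
#' @param average_members average twin maps over all ensemble members
#'   instead of using the reference model.
#' @return List of class `prototype_result`: `prototypes` (list of 3-D
#'   arrays), `assignment`, `r` (per matched subtype), `mean_r`.
#' @export
cvae_prototypes <- function(ensemble, data, clustering,
                            average_members = FALSE) {
  keep <- data$truth$group != "control"
  X <- data$volumes[, keep, drop = FALSE]
  groups <- data$truth$group[keep]
  models <- if (average_members) ensemble$models
            else list(reference_model(ensemble))
  tw <- Reduce(`+`, lapply(models, function(m)
    abs(synthetic_twin(m, X, groups)))) / length(models)
  shp <- data$config$template_shape
  proto <- lapply(seq_len(clustering$k) - 1L, function(cl) {
    members <- clustering$labels == cl
    if (!any(members)) {
      warning("empty cluster ", cl, " excluded")
      return(array(0, dim = shp))
    }
    array(rowMeans(tw[, members, drop = FALSE]), dim = shp)
  })
  score_prototypes(proto, data)
}

#' Cluster prototypes for the baseline VAE
#'
#' The literature-standard alternative: the prototype of a cluster is the
#' mean patient image of its members minus the mean control image; matching
#' and scoring as in [cvae_prototypes()] (correlations on absolute maps).
#'
#' @param data the `synthetic_dataset`.
#' @param clustering clustering of the patients (e.g. from VAE ensemble
#'   features).
#' @return A `prototype_result`.
#' @export
vae_prototypes <- function(data, clustering) {
  controls <- data$truth$group == "control"
  if (!any(controls)) stop("no controls in dataset")
  ctrl_mean <- rowMeans(data$volumes[, controls, drop = FALSE])
  Xp <- data$volumes[, !controls, drop = FALSE]
  shp <- data$config$template_shape
  proto <- lapply(seq_len(clustering$k) - 1L, function(cl) {
    members <- clustering$labels == cl
    if (!any(members)) {
      warning("empty cluster ", cl, " excluded")
      return(array(0, dim = shp))
    }
    array(abs(rowMeans(Xp[, members, drop = FALSE]) - ctrl_mean), dim = shp)
  })
  score_prototypes(proto, data)
}

score_prototypes <- function(proto, data) {
  k <- length(proto)
  gt <- lapply(seq_len(min(k, length(data$config$subtype_loci))),
               ground_truth_subtype_map, config = data$config)
  m <- match_prototypes(proto, gt, as.logical(data$template$brain_mask))
  structure(list(prototypes = proto, assignment = m$assignment, r = m$r,
                 mean_r = m$mean_r, correlation_matrix = m$correlation_matrix),
            class = "prototype_result")
}

#' @export
print.prototype_result <- function(x, ...) {
  cat(sprintf("%d cluster prototypes; matched Pearson r: %s (mean %.3f)\n",
              length(x$prototypes),
              paste(sprintf("%.3f", x$r), collapse = ", "), x$mean_r))
  invisible(x)
}

#' Disorder-selective difference maps from the comorbidity model
#'
#' For comorbid (disorder 1+2) subjects, reconstructs with the shared space
#' plus exactly one space of interest and subtracts the shared-only twin,
#' isolating the anatomy attributable to disorder 1, disorder 2, or the
#' comorbid (patient-shared) effect.
#'
#' @param model a fitted `comorbid_cvae`.
#' @param data a `synthetic_dataset` or voxel matrix (disorder 1+2
#'   subjects).
#' @param which `"d1"`, `"d2"` or `"comorbid"`.
#' @return voxels x subjects matrix of signed differences.
#' @export
comorbid_maps <- function(model, data, which = c("d1", "d2", "comorbid")) {
  which <- match.arg(which)
  if (model$spec$kind != "comorbid_cvae")
    stop("comorbid maps require a comorbid_cvae model")
  X <- if (inherits(data, "synthetic_dataset")) data$volumes else data
  enc <- encode(model, X)
  space <- switch(which, d1 = "d1", d2 = "d2", comorbid = "patient_shared")
  full <- decode(model, enc$mu, active = c("shared", space))
  twin <- decode(model, enc$mu, active = "shared")
  full - twin
}
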
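# Representational similarity analysis: latent and ground-truth magnitude
# dissimilarity matrices compared by Kendall's tau over their upper
# triangles.

#' Latent representational dissimilarity matrix
#'
#' Pairwise Euclidean distances between per-subject latent vectors in one
#' feature space.
#'
#' @param mu `latent_dim` x subjects matrix of posterior means, as returned
#'   by [encode()] (columns are subjects).
#' @param labels optional subject ids.
#' @return An `rdm`: symmetric non-negative matrix with zero diagonal.
#' @export
latent_rdm <- function(mu, labels = NULL) {
  m <- t(as.matrix(mu))                     # subjects x dims
  if (nrow(m) < 2) stop("need at least two subjects")
  d <- as.matrix(dist(m))
  if (is.null(labels)) labels <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  dimnames(d) <- list(labels, labels)
  structure(d, class = c("rdm", "matrix", "array"))
}

#' Ground-truth magnitude dissimilarity matrix
#'
#' Entry (i, j) is the absolute difference of the scalar effect magnitudes
#' of subjects i and j.
#'
#' @param magnitudes numeric vector of per-subject effect magnitudes.
#' @param labels optional subject ids.
#' @return An `rdm`.
#' @export
magnitude_rdm <- function(magnitudes, labels = NULL) {
  if (length(magnitudes) < 2) stop("need at least two subjects")
  d <- abs(outer(magnitudes, magnitudes, `-`))
  if (is.null(labels)) labels <- paste0("s", seq_along(magnitudes))
  dimnames(d) <- list(labels, labels)
  structure(d, class = c("rdm", "matrix", "array"))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM over %d subjects; dissimilarity range [%.4g, %.4g]\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' Kendall correlation between two RDMs
#'
#' Tie-corrected Kendall tau-b between the strictly-upper-triangle entries,
#' computed with an O(m log m) merge-sort algorithm. A constant upper
#' triangle on either side leaves the correlation undefined: `NA` is
#' returned with a warning.
#'
#' @param rdm_a,rdm_b matrices of identical dimension and label order.
#' @return Kendall's tau-b in `[-1, 1]`, or `NA`.
#' @export
rsa_correlation <- function(rdm_a, rdm_b) {
  if (!all(dim(rdm_a) == dim(rdm_b))) stop("RDMs must have the same shape")
  ut <- upper.tri(rdm_a)
  a <- rdm_a[ut]; b <- rdm_b[ut]
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    warning("constant upper triangle; Kendall tau undefined")
    return(NA_real_)
  }
  kendall_tau_b(a, b)
}

#' Ensemble-averaged RSA against a ground-truth effect
#'
#' For each ensemble member, builds the latent RDM of the requested feature
#' space and correlates it (Kendall tau) with the magnitude RDM of the
#' requested ground-truth effect; the reported value is the arithmetic mean
#' over members. Disorder-specific comparisons use patients only by default,
#' since controls carry an identically zero specific magnitude.
#'
#' @param ensemble a `cvae_ensemble` (or a single fitted `cvae`).
#' @param data a `synthetic_dataset` (training or held-out).
#' @param space feature space name (`"latent"` for the baseline VAE).
#' @param ground_truth `"shared"` or `"specific"`.
#' @param include_controls include controls in the disorder-specific
#'   comparison.
#' @return List of class `rsa_result`: `tau`, `per_model_taus`, `n_pairs`,
#'   `feature_space`, `ground_truth`.
#' @export
ensemble_rsa <- function(ensemble, data, space = "specific",
                         ground_truth = c("specific", "shared"),
                         include_controls = FALSE) {
  ground_truth <- match.arg(ground_truth)
  models <- if (inherits(ensemble, "cvae_ensemble")) ensemble$models
            else list(ensemble)
  keep <- if (ground_truth == "specific" && !include_controls)
    data$truth$group != "control" else rep(TRUE, nrow(data$truth))
  mags <- data$truth[[paste0(ground_truth, "_mag")]][keep]
  gt_rdm <- magnitude_rdm(mags)
  X <- data$volumes[, keep, drop = FALSE]
  taus <- vapply(models, function(m) {
    mu <- encode(m, X)$mu[[space]]
    if (is.null(mu)) stop("model has no feature space '", space, "'")
    rsa_correlation(latent_rdm(mu), gt_rdm)
  }, 0)
  structure(list(tau = mean(taus), per_model_taus = taus,
                 n_pairs = sum(keep) * (sum(keep) - 1) / 2,
                 feature_space = space, ground_truth = ground_truth),
            class = "rsa_result")
}

#' @export
print.rsa_result <- function(x, ...) {
  cat(sprintf("RSA %s latents vs %s ground truth: tau = %.4f (%d models, %d pairs)\n",
              x$feature_space, x$ground_truth, x$tau,
              length(x$per_model_taus), x$n_pairs))
  invisible(x)
}

#' t-test on Fisher z-transformed correlations
#'
#' Applies `atanh` to each correlation, then a Student's t-test: two-sample
#' with pooled variance (df = n_a + n_b - 2) or paired.
#'
#' @param taus_a,taus_b correlation samples (each of length >= 2, strictly
#'   inside (-1, 1)).
#' @param paired paired test instead of two-sample.
#' @return List with `t`, `df`, `p`.
#' @export
fisher_z_ttest <- function(taus_a, taus_b, paired = FALSE) {
  if (any(abs(c(taus_a, taus_b)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  za <- atanh(taus_a); zb <- atanh(taus_b)
  ht <- t.test(za, zb, paired = paired, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Variance explained by reconstructions
#'
#' `1 - SSE / SST` over all voxels of all subjects, with reconstructions
#' from the posterior means; for an ensemble, the mean over members.
#'
#' @param model a fitted `cvae` or `cvae_ensemble`.
#' @param data a `synthetic_dataset`.
#' @export
variance_explained <- function(model, data) {
  if (inherits(model, "cvae_ensemble"))
    return(mean(vapply(model$models, variance_explained, 0, data = data)))
  X <- data$volumes
  sst <- sum((X - mean(X))^2)
  if (sst == 0) stop("constant input set; variance explained undefined")
  rec <- predict(model, data, type = "reconstruction")
  1 - sum((X - rec)^2) / sst
}

#' PCA baseline with out-of-sample transfer
#'
#' Fits principal components on the training volumes (masked voxels),
#' keeping the smallest number of components whose cumulative variance
#' reaches `variance_floor`; scores both the training and held-out sets with
#' the same loadings; and correlates each score-space RDM with the
#' disorder-specific ground-truth RDM (patients only).
#'
#' @param train,heldout `synthetic_dataset`s from the same design.
#' @param variance_floor fraction of variance the retained components must
#'   explain.
#' @return List with `n_components`, `variance_explained`, `tau_train`,
#'   `tau_transfer`.
#' @export
pca_baseline <- function(train, heldout, variance_floor = 0.85) {
  stopifnot(variance_floor > 0, variance_floor < 1)
  mask <- as.logical(train$template$brain_mask)
  Xtr <- t(train$volumes[mask, , drop = FALSE])
  pc <- prcomp(Xtr, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= variance_floor)[1]
  if (is.na(k)) stop("variance floor unreachable")
  score_tau <- function(ds) {
    keep <- ds$truth$group != "control"
    Xm <- t(ds$volumes[mask, keep, drop = FALSE])
    sc <- sweep(Xm, 2, pc$center) %*% pc$rotation[, seq_len(k), drop = FALSE]
    rsa_correlation(latent_rdm(t(sc)),
                    magnitude_rdm(ds$truth$specific_mag[keep]))
  }
  list(n_components = k, variance_explained = cum[k],
       tau_train = score_tau(train), tau_transfer = score_tau(heldout))
}
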
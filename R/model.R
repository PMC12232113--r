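#' Model specification for the VAE family
#'
#' All three model kinds share the same stack: per feature space an encoder
#' of two stride-2 3-D convolutions (kernel 3, ReLU) followed by dense maps
#' to the posterior mean and log-variance; a single decoder takes the
#' concatenated latent spaces through a dense layer and two transposed
#' convolutions with a final sigmoid. Kinds differ in their feature spaces:
#'
#' * `vae` — one space, always active, with doubled convolution filters
#'   (the non-contrastive baseline);
#' * `cvae` — `shared` + `specific`; controls are decoded with the specific
#'   latents replaced by zeros;
#' * `comorbid_cvae` — `shared`, `patient_shared`, `d1`, `d2`; each group
#'   activates only its spaces (see [active_spaces()]).
#'
#' @param kind `"cvae"`, `"vae"` or `"comorbid_cvae"`.
#' @param input_shape cubic voxel grid, side divisible by 4.
#' @param latent_dim latent dimensions per feature space.
#' @param conv_filters two per-layer filter counts (doubled internally for
#'   `vae`).
#' @param learning_rate Adam step size.
#' @param kl_weight weight of the KL term in the loss.
#' @param batch_size minibatch size.
#' @param kl_all_spaces if `TRUE` (default), the KL term penalizes every
#'   feature space for every subject, including spaces zeroed in that
#'   subject's reconstruction. Penalizing a control's specific-space
#'   posterior forces the specific encoder to be invariant to shared
#'   variation, which is what makes the contrastive split work; `FALSE`
#'   restores the active-spaces-only variant.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("cvae", "vae", "comorbid_cvae"),
                       input_shape = c(64, 64, 64),
                       latent_dim = 2,
                       conv_filters = c(32, 64),
                       learning_rate = 1e-3,
                       kl_weight = 1.0,
                       batch_size = 32,
                       kl_all_spaces = TRUE) {
  kind <- match.arg(kind)
  input_shape <- as.integer(input_shape)
  if (length(unique(input_shape)) != 1 || input_shape[1] %% 4 != 0)
    stop("input_shape must be cubic with side divisible by 4")
  if (latent_dim < 1) stop("latent_dim must be >= 1")
  spaces <- switch(kind,
    vae = "latent",
    cvae = c("shared", "specific"),
    comorbid_cvae = c("shared", "patient_shared", "d1", "d2"))
  filters <- if (kind == "vae") 2L * as.integer(conv_filters)
             else as.integer(conv_filters)
  structure(list(kind = kind, input_shape = input_shape,
                 latent_dim = as.integer(latent_dim),
                 conv_filters = filters,
                 learning_rate = learning_rate, kl_weight = kl_weight,
                 batch_size = as.integer(batch_size),
                 kl_all_spaces = kl_all_spaces,
                 spaces = spaces),
            class = "model_spec")
}

spec_dims <- function(spec) {
  list(D = spec$input_shape[1], S = length(spec$spaces),
       d = spec$latent_dim, f1 = spec$conv_filters[1],
       f2 = spec$conv_filters[2])
}

#' Feature spaces active for a subject group
#'
#' Inactive spaces are replaced by zero vectors at the decoder input, both
#' in training and in analysis-time reconstructions.
#'
#' @param spec a [model_spec()].
#' @param groups character vector of group labels.
#' @return Logical matrix, spaces x subjects.
#' @export
active_spaces <- function(spec, groups) {
  S <- length(spec$spaces)
  m <- matrix(FALSE, S, length(groups),
              dimnames = list(spec$spaces, NULL))
  if (spec$kind == "vae") {
    m[1, ] <- TRUE
  } else if (spec$kind == "cvae") {
    m["shared", ] <- TRUE
    m["specific", ] <- groups != "control"
  } else {
    known <- c("control", "disorder1", "disorder2", "disorder1+2")
    if (!all(groups %in% known))
      stop("unknown group for comorbid_cvae: ",
           paste(setdiff(groups, known), collapse = ", "))
    m["shared", ] <- TRUE
    m["patient_shared", ] <- groups != "control"
    m["d1", ] <- groups %in% c("disorder1", "disorder1+2")
    m["d2", ] <- groups %in% c("disorder2", "disorder1+2")
  }
  m
}

# He-style initialization; all draws from the current RNG stream.
init_weights <- function(spec) {
  dm <- spec_dims(spec)
  N2 <- (dm$D / 4)^3
  F <- dm$f2 * N2
  he <- function(nr, nc, fan) matrix(rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  zeros <- function(nr) matrix(0, nr, 1)
  w <- list()
  for (s in seq_len(dm$S)) {
    w[[paste0("W1_", s)]] <- he(dm$f1, 27, 27)
    w[[paste0("b1_", s)]] <- zeros(dm$f1)
    w[[paste0("W2_", s)]] <- he(dm$f2, 27 * dm$f1, 27 * dm$f1)
    w[[paste0("b2_", s)]] <- zeros(dm$f2)
    w[[paste0("Wmu_", s)]] <- he(dm$d, F, F)
    w[[paste0("bmu_", s)]] <- zeros(dm$d)
    w[[paste0("Wlv_", s)]] <- he(dm$d, F, F) * 0.1
    w[[paste0("blv_", s)]] <- zeros(dm$d)
  }
  w$Wd <- he(F, dm$S * dm$d, dm$S * dm$d)
  w$bd <- zeros(F)
  w$V1 <- he(dm$f2, 27 * dm$f1, 27 * dm$f2)
  w$c1 <- zeros(dm$f1)
  w$V2 <- he(dm$f1, 27, 27 * dm$f1)
  w$c2 <- zeros(1)
  w
}

#' Fit a (contrastive) variational autoencoder
#'
#' The main fitting function. Trains the network of `spec` on the volumes of
#' a [generate_dataset()] cohort with minibatch Adam. Every random draw
#' (weight initialization, shuffling, reparameterization noise) derives from
#' `seed`, so a fit is exactly reproducible; a fit can later be continued
#' with [train_more()] and remains deterministic regardless of where it was
#' interrupted.
#'
#' @param data a `synthetic_dataset`, or a list with `volumes` (voxels x
#'   subjects matrix in `[0, 1]`) and `truth$group`.
#' @param kind model kind, used when `spec` is not given.
#' @param epochs number of training epochs.
#' @param spec a [model_spec()]; defaults to `model_spec(kind,
#'   input_shape = <data grid>)`.
#' @param seed integer seed for this fit.
#' @param verbose print the loss every few epochs.
#' @return An object of class `cvae` with elements `weights`, `spec`,
#'   `history` (per-epoch `mse`, `kl`), `seed`, `epochs`, `flagged`
#'   (non-finite loss encountered). Methods: `print`, `summary`, `predict`,
#'   `residuals`, `simulate`, `plot`.
#' @seealso [cvae_ensemble()] for the two-stage ensemble procedure.
#' @export
cvae <- function(data, kind = "cvae", epochs = 30, spec = NULL, seed = 1,
                 verbose = FALSE) {
  X <- data$volumes
  groups <- data$truth$group
  if (is.null(spec)) {
    side <- round(nrow(X)^(1 / 3))
    spec <- model_spec(kind, input_shape = rep(side, 3))
  }
  if (nrow(X) != prod(spec$input_shape))
    stop("volume size does not match spec input_shape")
  object <- structure(list(
    weights = with_seed(derive_seed(seed, 0), init_weights(spec)),
    spec = spec, seed = as.integer(seed), epochs = 0L,
    adam = NULL, step = 0L,
    history = data.frame(epoch = integer(), mse = numeric(), kl = numeric()),
    flagged = FALSE), class = "cvae")
  train_more(object, data, epochs, verbose = verbose)
}

#' Continue training a fitted model
#'
#' @param object a fitted [cvae()] model.
#' @param data the training data (same subjects and order as the original
#'   fit for exact reproducibility).
#' @param epochs additional epochs.
#' @inheritParams cvae
#' @return The updated `cvae` object.
#' @export
train_more <- function(object, data, epochs, verbose = FALSE) {
  spec <- object$spec
  dm <- spec_dims(spec)
  X <- data$volumes
  n <- ncol(X)
  mask <- active_spaces(spec, data$truth$group) * 1.0
  kl_mask <- if (isTRUE(spec$kl_all_spaces)) (mask * 0 + 1) else mask
  if (is.null(object$adam)) {
    zero <- lapply(object$weights, function(w) w * 0)
    object$adam <- list(m = zero, v = zero)
  }
  for (ep in seq_len(epochs)) {
    epoch_id <- object$epochs + ep
    st <- with_seed(derive_seed(object$seed, epoch_id), {
      ord <- sample.int(n) - 1L
      eps <- lapply(seq_len(dm$S), function(s) matrix(rnorm(dm$d * n), dm$d, n))
      nn_train_epoch(object$weights, object$adam$m, object$adam$v,
                     object$step, X, mask, kl_mask, eps, ord, dm,
                     spec$learning_rate, spec$kl_weight, spec$batch_size)
    })
    object$weights <- st$weights
    object$adam <- list(m = st$m, v = st$v)
    object$step <- st$step
    object$history <- rbind(object$history,
                            data.frame(epoch = epoch_id, mse = st$mse, kl = st$kl))
    if (!is.finite(st$mse) || !is.finite(st$kl)) {
      object$flagged <- TRUE
      object$epochs <- object$epochs + ep
      warning("non-finite loss at epoch ", epoch_id, "; model flagged")
      return(object)
    }
    if (verbose && (epoch_id %% 5 == 0 || ep == epochs))
      message(sprintf("epoch %3d  mse %.4f  kl %.4f", epoch_id, st$mse, st$kl))
  }
  object$epochs <- object$epochs + epochs
  object
}

#' Encode volumes into latent codes
#'
#' Returns the deterministic posterior means and log-variances per feature
#' space. The specific-space code is produced for every subject, controls
#' included; the zero substitution happens only at decoding.
#'
#' @param object a fitted `cvae`.
#' @param volumes voxels x subjects matrix (or a `synthetic_dataset`).
#' @return List with `mu` and `logvar`: each a named list (one `latent_dim`
#'   x subjects matrix per feature space).
#' @export
encode <- function(object, volumes) {
  if (inherits(volumes, "synthetic_dataset")) volumes <- volumes$volumes
  if (is.null(dim(volumes))) volumes <- matrix(volumes, ncol = 1)
  if (nrow(volumes) != prod(object$spec$input_shape))
    stop("volume size does not match model input shape")
  enc <- nn_encode(object$weights, volumes, spec_dims(object$spec))
  names(enc$mu) <- names(enc$logvar) <- object$spec$spaces
  enc
}

#' Decode latent codes into volumes
#'
#' Concatenates the feature spaces, substituting zeros for spaces inactive
#' for each subject's group (or for spaces explicitly dropped via `active`),
#' and runs the decoder.
#'
#' @param object a fitted `cvae`.
#' @param latents named list of `latent_dim` x subjects matrices (typically
#'   `encode(...)$mu`).
#' @param groups group labels (length 1 or one per subject), mapped to
#'   active spaces via [active_spaces()]. Ignored when `active` is given.
#' @param active optional character vector naming the active spaces
#'   directly.
#' @return Voxels x subjects matrix of reconstructions in `[0, 1]`.
#' @export
decode <- function(object, latents, groups = NULL, active = NULL) {
  spec <- object$spec
  n <- ncol(latents[[1]])
  if (is.null(active)) {
    if (is.null(groups)) stop("supply either groups or active")
    if (length(groups) == 1) groups <- rep(groups, n)
    mask <- active_spaces(spec, groups)
  } else {
    if (!all(active %in% spec$spaces))
      stop("unknown space: ", paste(setdiff(active, spec$spaces), collapse = ", "))
    mask <- matrix(spec$spaces %in% active, length(spec$spaces), n)
  }
  d <- spec$latent_dim
  Z <- matrix(0, length(spec$spaces) * d, n)
  for (s in seq_along(spec$spaces)) {
    z <- latents[[spec$spaces[s]]]
    if (is.null(z)) stop("missing latents for space ", spec$spaces[s])
    Z[(s - 1) * d + seq_len(d), ] <- z * rep(mask[s, ], each = d)
  }
  nn_decode(object$weights, Z, spec_dims(spec))
}

#' Reparameterized Gaussian sample
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps` standard normal.
#'
#' @param mu,logvar numeric vectors or matrices of equal size.
#' @param eps optional noise (drawn from the current RNG stream if missing).
#' @export
reparameterize <- function(mu, logvar, eps = NULL) {
  stopifnot(length(mu) == length(logvar))
  if (is.null(eps)) eps <- array(rnorm(length(mu)), dim = dim(mu) %||% length(mu))
  mu + exp(logvar / 2) * eps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the loss on a dataset
#'
#' Deterministic evaluation: reconstructions use the posterior means. MSE is
#' the squared reconstruction error summed over voxels and averaged over
#' subjects; KL is the closed-form Gaussian divergence summed over the
#' latent coordinates of each subject's active spaces and averaged over
#' subjects.
#'
#' @param object a fitted `cvae`.
#' @param data a `synthetic_dataset` (or compatible list).
#' @return List with `mse`, `kl` and `total = mse + kl_weight * kl`.
#' @export
evaluate_loss <- function(object, data) {
  spec <- object$spec
  X <- if (inherits(data, "synthetic_dataset") || is.list(data)) data$volumes else data
  groups <- data$truth$group
  enc <- encode(object, X)
  rec <- decode(object, enc$mu, groups = groups)
  mse <- mean(colSums((X - rec)^2))
  mask <- active_spaces(spec, groups)
  if (spec$kl_all_spaces) mask[] <- TRUE
  kl_per <- vapply(seq_along(spec$spaces), function(s) {
    k <- 0.5 * colSums(enc$mu[[s]]^2 + exp(enc$logvar[[s]]) - 1 -
                         enc$logvar[[s]])
    mean(k * mask[s, ])
  }, 0)
  kl <- sum(kl_per)
  list(mse = mse, kl = kl, total = mse + spec$kl_weight * kl)
}

#' Closed-form Gaussian KL divergence
#'
#' `KL(N(mu, exp(logvar)) || N(0, 1))` summed over coordinates.
#'
#' @param mu,logvar numeric vectors.
#' @export
kl_divergence <- function(mu, logvar) {
  sum(0.5 * (mu^2 + exp(logvar) - 1 - logvar))
}

#' @export
print.cvae <- function(x, ...) {
  cat(sprintf("%s model: %s input, %d space(s) x %d latents, %d epochs%s\n",
              x$spec$kind, paste(x$spec$input_shape, collapse = "x"),
              length(x$spec$spaces), x$spec$latent_dim, x$epochs,
              if (x$flagged) " [FLAGGED: non-finite loss]" else ""))
  if (nrow(x$history))
    cat(sprintf("  final loss: mse %.4f, kl %.4f\n",
                tail(x$history$mse, 1), tail(x$history$kl, 1)))
  invisible(x)
}

#' @export
summary.cvae <- function(object, ...) {
  npar <- sum(vapply(object$weights, length, 0L))
  cat(sprintf("%s: %d parameters, filters (%s), lr %g, kl_weight %g\n",
              object$spec$kind, npar,
              paste(object$spec$conv_filters, collapse = ", "),
              object$spec$learning_rate, object$spec$kl_weight))
  print(object)
  invisible(object)
}

#' Predictions from a fitted model
#'
#' @param object a fitted `cvae`.
#' @param newdata a `synthetic_dataset` or voxels x subjects matrix.
#' @param type `"latent"` (posterior means per space), `"reconstruction"`
#'   (decoded volumes using each subject's active spaces), or `"twin"`
#'   (shared-only counterfactual reconstructions).
#' @param groups group labels when `newdata` is a bare matrix.
#' @param ... unused.
#' @export
predict.cvae <- function(object, newdata,
                         type = c("latent", "reconstruction", "twin"),
                         groups = NULL, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "synthetic_dataset")) newdata$volumes else newdata
  if (is.null(groups) && inherits(newdata, "synthetic_dataset"))
    groups <- newdata$truth$group
  enc <- encode(object, X)
  if (type == "latent") return(enc$mu)
  if (type == "reconstruction") {
    if (is.null(groups)) stop("groups needed for reconstructions")
    return(decode(object, enc$mu, groups = groups))
  }
  if (object$spec$kind == "vae")
    stop("twin reconstructions require a contrastive model")
  decode(object, enc$mu, active = "shared")
}

#' @export
residuals.cvae <- function(object, data, ...) {
  X <- if (inherits(data, "synthetic_dataset")) data$volumes else data
  rec <- predict(object, data, type = "reconstruction")
  X - rec
}

#' Draw new volumes from the generative model
#'
#' Samples latent codes from the standard-normal prior for each requested
#' group (inactive spaces zeroed) and decodes them.
#'
#' @param object a fitted `cvae`.
#' @param nsim number of volumes.
#' @param seed RNG seed.
#' @param groups group label(s) for the draws.
#' @param ... unused.
#' @export
simulate.cvae <- function(object, nsim = 1, seed = NULL,
                          groups = "patient", ...) {
  spec <- object$spec
  if (spec$kind == "vae") groups <- "control"  # any label; all spaces active
  if (length(groups) == 1) groups <- rep(groups, nsim)
  draw <- function() {
    lat <- lapply(spec$spaces, function(s)
      matrix(rnorm(spec$latent_dim * nsim), spec$latent_dim, nsim))
    names(lat) <- spec$spaces
    lat
  }
  lat <- if (is.null(seed)) draw() else with_seed(seed, draw())
  decode(object, lat, groups = groups)
}

#' @export
plot.cvae <- function(x, ...) {
  if (!nrow(x$history)) stop("no training history")
  graphics::plot(x$history$epoch, x$history$mse, type = "l",
                 xlab = "epoch", ylab = "reconstruction MSE",
                 main = paste(x$spec$kind, "training loss"), ...)
  invisible(x)
}
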
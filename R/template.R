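#' Procedural template brain phantom
#'
#' Builds a brain-like template volume: a smoothed ellipsoidal "cortex" of
#' intermediate intensity containing several interior structures (smooth
#' Gaussian blobs of distinct brighter and darker intensity), so that even
#' sub-voxel deformations produce visible intensity change. The phantom
#' stands in for a real anatomical template; [read_template()] loads a
#' user-supplied NIfTI template instead.
#'
#' @param shape integer length-3 vector of voxel counts, each >= 16.
#' @param seed integer; controls the jitter of interior structure positions
#'   and intensities. The same `(shape, seed)` always yields a bitwise
#'   identical volume.
#' @param spacing voxel edge length in arbitrary units.
#' @return An object of class `template_volume`: a list with `grid` (3-D
#'   array of intensities in `[0, 1]`), `brain_mask` (3-D logical array),
#'   `shape`, and `spacing`.
#' @examples
#' tpl <- make_template(c(16, 16, 16), seed = 1)
#' range(tpl$grid)
#' mean(tpl$brain_mask)
#' @export
make_template <- function(shape = c(64, 64, 64), seed = 0, spacing = 1.0) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop("shape must have three components, each >= 16")
  semi <- c(0.42, 0.36, 0.38) * shape    # ellipsoid semi-axes, voxels
  ctr <- (shape - 1) / 2

  # interior structures in normalized ellipsoid coordinates; the last five
  # are compact nuclei at the canonical focal-effect positions, so that
  # deformations there act on sharp intensity structure
  blobs <- list(
    list(p = c( 0.00,  0.15,  0.10), w = 0.34, a =  0.35),  # central bright mass
    list(p = c( 0.45, -0.35,  0.05), w = 0.22, a = -0.22),
    list(p = c(-0.45, -0.35,  0.05), w = 0.22, a = -0.22),
    list(p = c( 0.40,  0.45, -0.15), w = 0.20, a =  0.30),
    list(p = c(-0.40,  0.45, -0.15), w = 0.20, a =  0.30),
    list(p = c( 0.00, -0.55, -0.20), w = 0.25, a =  0.25),
    list(p = c( 0.30,  0.00,  0.40), w = 0.20, a = -0.25),
    list(p = c(-0.30,  0.00,  0.40), w = 0.20, a =  0.28),
    list(p = c( 0.28, -0.25, -0.40), w = 0.20, a =  0.26),
    list(p = c(-0.28,  0.25, -0.40), w = 0.20, a = -0.24),
    list(p = c( 0.55,  0.05,  0.12), w = 0.18, a =  0.42),
    list(p = c(-0.55,  0.05,  0.12), w = 0.18, a =  0.38),
    list(p = c( 0.00,  0.58, -0.12), w = 0.18, a =  0.40),
    list(p = c( 0.00, -0.58, -0.12), w = 0.18, a =  0.36),
    list(p = c( 0.00,  0.05, -0.60), w = 0.18, a =  0.38)
  )
  jit <- with_seed(seed, list(
    dp = matrix(runif(3 * length(blobs), -0.04, 0.04), ncol = 3),
    da = runif(length(blobs), -0.04, 0.04)
  ))

  # normalized coordinates per axis
  gx <- (seq_len(shape[1]) - 1 - ctr[1]) / semi[1]
  gy <- (seq_len(shape[2]) - 1 - ctr[2]) / semi[2]
  gz <- (seq_len(shape[3]) - 1 - ctr[3]) / semi[3]
  ex2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)   # squared ellipsoid radius
  er <- sqrt(ex2)

  vol <- array(0.35, dim = shape)
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    p <- b$p + jit$dp[i, ]
    a <- b$a + jit$da[i]
    d2 <- outer(outer((gx - p[1])^2, (gy - p[2])^2, `+`), (gz - p[3])^2, `+`)
    vol <- vol + a * exp(-d2 / (2 * b$w^2))
  }
  # smooth edge ramp: full intensity for er <= 0.9, zero at er >= 1
  edge <- pmin(1, pmax(0, (1 - er) / 0.1))
  edge <- edge * edge * (3 - 2 * edge)
  vol <- array(pmin(1, pmax(0, vol)) * edge, dim = shape)
  mask <- er <= 1

  out <- structure(
    list(grid = vol, brain_mask = mask, shape = shape, spacing = spacing),
    class = "template_volume")
  validate_template(out)
  out
}

validate_template <- function(x) {
  stopifnot(inherits(x, "template_volume"))
  if (!all(is.finite(x$grid)) || any(x$grid < 0) || any(x$grid > 1))
    stop("template intensities must be finite and within [0, 1]")
  frac <- mean(x$brain_mask)
  if (frac <= 0.05 || frac >= 0.80)
    stop("brain mask covers ", round(100 * frac, 1),
         "% of voxels; expected between 5% and 80%")
  if (any(x$grid[!x$brain_mask] != 0))
    stop("intensity must be 0 outside the brain mask")
  invisible(x)
}

#' @export
print.template_volume <- function(x, ...) {
  cat("Template volume:", paste(x$shape, collapse = " x "),
      "voxels, spacing", x$spacing, "\n")
  cat(sprintf("  brain mask: %d voxels (%.1f%%); intensity range [%.3f, %.3f]\n",
              sum(x$brain_mask), 100 * mean(x$brain_mask),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Read and write template volumes as NIfTI-1
#'
#' `write_volume()` stores a 3-D grid as `.nii.gz` with an identity affine
#' scaled by the voxel spacing; `read_template()` loads a NIfTI volume,
#' rescales intensities to `[0, 1]`, and derives a brain mask by thresholding
#' at a small fraction of the maximum intensity.
#'
#' @param x a `template_volume` or a 3-D array.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param spacing voxel edge length recorded in the header.
#' @param mask_threshold intensity fraction below which voxels are considered
#'   background.
#' @return `read_template()` returns a `template_volume`.
#' @export
write_volume <- function(x, path, spacing = 1.0) {
  grid <- if (inherits(x, "template_volume")) x$grid else x
  if (inherits(x, "template_volume")) spacing <- x$spacing
  img <- RNifti::asNifti(grid, pixdim = rep(spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_template <- function(path, mask_threshold = 0.01) {
  img <- RNifti::readNifti(path)
  grid <- as.array(img)
  if (length(dim(grid)) != 3) stop("expected a 3-D NIfTI volume")
  rng <- range(grid, finite = TRUE)
  if ((rng[1] < 0 || rng[2] > 1) && rng[2] > rng[1])
    grid <- (grid - rng[1]) / (rng[2] - rng[1])
  mask <- grid > mask_threshold
  grid[!mask] <- 0
  spacing <- tryCatch(RNifti::pixdim(img)[1], error = function(e) 1.0)
  out <- structure(
    list(grid = grid, brain_mask = mask, shape = dim(grid),
         spacing = as.numeric(spacing)),
    class = "template_volume")
  validate_template(out)
  out
}
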
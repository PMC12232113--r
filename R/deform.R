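#' Sphere-pair radial deformation
#'
#' A single expansion or contraction effect parameterized by a pair of
#' concentric spheres: a reference sphere of radius `r_ref` is mapped onto a
#' target sphere of radius `r_tar`. The induced displacement at distance
#' `rho` from the center is radial with magnitude `m(rho)` that rises
#' linearly from 0 at the center to `r_tar - r_ref` on the reference surface
#' and decays linearly back to 0 at the support radius, beyond which the
#' field is exactly zero. `r_tar > r_ref` expands tissue, `r_tar < r_ref`
#' compresses it; `r_tar == r_ref` is the identity.
#'
#' @param center numeric length-3 voxel coordinate (0-based, may be
#'   fractional).
#' @param r_ref,r_tar reference and target sphere radii in voxels, both
#'   positive and smaller than `r_support`.
#' @param r_support outer radius beyond which the displacement is exactly
#'   zero; defaults to `2.5 * r_ref`.
#' @return An object of class `sphere_deformation`.
#' @examples
#' sp <- sphere_deformation(c(8, 8, 8), r_ref = 4, r_tar = 5)
#' radial_displacement(c(12, 8, 8), sp)  # (+1, 0, 0): surface maps ref -> tar
#' @export
sphere_deformation <- function(center, r_ref, r_tar, r_support = 2.5 * r_ref) {
  center <- as.numeric(center)
  if (length(center) != 3) stop("center must be a 3-D coordinate")
  if (r_ref <= 0 || r_tar <= 0) stop("sphere radii must be positive")
  if (r_support <= max(r_ref, r_tar))
    stop("r_support must exceed max(r_ref, r_tar)")
  structure(list(center = center, r_ref = r_ref, r_tar = r_tar,
                 r_support = r_support),
            class = "sphere_deformation")
}

#' @export
print.sphere_deformation <- function(x, ...) {
  cat(sprintf("Sphere deformation at (%.1f, %.1f, %.1f): r_ref=%.2f -> r_tar=%.2f (support %.2f)\n",
              x$center[1], x$center[2], x$center[3], x$r_ref, x$r_tar, x$r_support))
  invisible(x)
}

#' Radial displacement of one sphere pair at given points
#'
#' @param points numeric vector of length 3, or an `m x 3` matrix of
#'   coordinates.
#' @param sphere a [sphere_deformation()].
#' @return An `m x 3` matrix (or length-3 vector for a single point) of
#'   displacement vectors in voxels.
#' @export
radial_displacement <- function(points, sphere) {
  single <- is.null(dim(points))
  p <- if (single) matrix(as.numeric(points), nrow = 1) else as.matrix(points)
  d <- sweep(p, 2, sphere$center)
  rho <- sqrt(rowSums(d^2))
  amp <- sphere$r_tar - sphere$r_ref
  m <- numeric(length(rho))
  inside <- rho <= sphere$r_ref & rho > 0
  ring <- rho > sphere$r_ref & rho < sphere$r_support
  m[inside] <- amp * rho[inside] / sphere$r_ref
  m[ring] <- amp * (sphere$r_support - rho[ring]) /
    (sphere$r_support - sphere$r_ref)
  scale <- ifelse(rho > 0, m / rho, 0)
  out <- d * scale
  if (single) drop(out) else out
}

#' Voxelwise deformation field from a set of sphere pairs
#'
#' Superposes the radial displacements of all spheres on the voxel grid.
#' An empty sphere list gives the zero field. Spheres whose support ball
#' extends past the grid boundary trigger a warning; the field is simply
#' evaluated on (clipped at) the grid.
#'
#' @param spheres list of [sphere_deformation()] objects (may be empty).
#' @param shape integer length-3 voxel counts of the target grid.
#' @return An object of class `deformation_field`: a `prod(shape) x 3`
#'   displacement matrix with a `shape` attribute, voxel index `v` ordered
#'   x-fastest (matching `array(..., dim = shape)`).
#' @export
build_field <- function(spheres, shape) {
  shape <- as.integer(shape)
  V <- prod(shape)
  disp <- matrix(0, nrow = V, ncol = 3)
  if (length(spheres)) {
    pts <- as.matrix(expand.grid(x = seq_len(shape[1]) - 1,
                                 y = seq_len(shape[2]) - 1,
                                 z = seq_len(shape[3]) - 1))
    for (sp in spheres) {
      stopifnot(inherits(sp, "sphere_deformation"))
      if (any(sp$center - sp$r_support < 0) ||
          any(sp$center + sp$r_support > shape - 1))
        warning("sphere support extends outside the grid; field clipped at boundary")
      disp <- disp + radial_displacement(pts, sp)
    }
  }
  structure(disp, shape = shape, class = c("deformation_field", "matrix", "array"))
}

#' @export
print.deformation_field <- function(x, ...) {
  nrm <- sqrt(rowSums(unclass(x)^2))
  cat("Deformation field on", paste(attr(x, "shape"), collapse = " x "),
      sprintf("grid; nonzero at %d voxels; max |u| = %.3f\n",
              sum(nrm > 0), max(nrm)))
  invisible(x)
}

#' Warp a volume by a deformation field
#'
#' Pull-back (inverse) warping: output voxel `v` takes the trilinearly
#' interpolated intensity of the input at `v - u(v)` where `u` is the
#' displacement. Samples outside the grid read 0; output intensities are
#' clipped to `[0, 1]`. The warped volume's brain mask is recomputed as the
#' set of voxels with positive intensity, since a global expansion can move
#' tissue past the template's mask boundary.
#'
#' @param volume a `template_volume`.
#' @param field a `deformation_field` with matching shape.
#' @return A `template_volume` of the same shape.
#' @export
warp <- function(volume, field) {
  stopifnot(inherits(volume, "template_volume"),
            inherits(field, "deformation_field"))
  if (!all(attr(field, "shape") == volume$shape))
    stop("field shape does not match volume shape")
  out <- warp_pullback(as.numeric(volume$grid), unclass(field),
                       as.integer(volume$shape))
  out <- pmin(1, pmax(0, out))
  grid <- array(out, dim = volume$shape)
  structure(list(grid = grid, brain_mask = grid > 0,
                 shape = volume$shape, spacing = volume$spacing),
            class = "template_volume")
}

#' Mean displacement magnitude over a mask
#'
#' Mean Euclidean norm of the displacement vectors over the masked voxels,
#' used to verify the relative magnitude of shared versus disorder-specific
#' deformation fields.
#'
#' @param field a `deformation_field`.
#' @param mask logical array or vector selecting voxels; must select at
#'   least one voxel.
#' @return Non-negative scalar.
#' @export
mean_displacement <- function(field, mask) {
  m <- as.logical(mask)
  if (!any(m)) stop("mask selects no voxels")
  u <- unclass(field)[m, , drop = FALSE]
  mean(sqrt(rowSums(u^2)))
}
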
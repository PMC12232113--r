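# Dataset designs: five synthetic cohorts with known ground truth.
#   1: one disorder locus, graded severity only
#   2-4: patients split over 2 / 3 / 5 subtypes with subtype-specific loci
#   5: comorbidity -- disorder 1, disorder 2 and disorder 1+2 groups, each
#      with a unique locus plus one locus common to all patient groups.

# canonical interior locus positions, unit-ellipsoid coordinates; the
# fourth entry is the locus's fixed deformation direction (+1 expansion,
# -1 compression), one consistent direction per locus
.locus_table <- rbind(
  c( 0.55,  0.05,  0.12,  1),
  c(-0.55,  0.05,  0.12, -1),
  c( 0.00,  0.58, -0.12,  1),
  c( 0.00, -0.58, -0.12, -1),
  c( 0.00,  0.05, -0.60,  1)
)

#' Generation configuration for a synthetic cohort
#'
#' Defines one of the five dataset designs. Deformation effects are
#' parameterized by sphere pairs whose two radii are drawn independently and
#' uniformly from a radius interval, so the signed diameter difference
#' follows a symmetric triangular distribution (expansion or compression
#' with equal probability). The default radius intervals are calibrated so
#' that the shared field's mean voxelwise displacement over the brain mask
#' is on average 2.4x that of the disorder-specific field (see
#' [calibrate_ratio()]).
#'
#' @param dataset_id integer 1-5 selecting the design.
#' @param n_controls,n_patients group sizes.
#' @param template_shape,template_seed passed to [make_template()].
#' @param shared_radius_range interval (fraction of the smallest grid side)
#'   from which the shared sphere's two radii are drawn.
#' @param specific_radius_range interval (fraction of grid side) for the
#'   reference radius of each disorder-specific locus.
#' @param specific_delta_range interval (fraction of grid side) for the
#'   absolute radius difference `|r_tar - r_ref|` of a focal sphere pair,
#'   applied in the locus's fixed direction (expansion or compression).
#' @param shared_support,specific_support_factor support radius of the shared
#'   sphere (fraction of grid side) and the support/reference ratio of the
#'   focal spheres.
#' @param subtype_loci optional list (one entry per subtype) of lists of
#'   unit-ellipsoid locus coordinates; defaults to the design's canonical
#'   maximally separated positions.
#' @param comorbid_loci list of loci applied to every patient group
#'   (dataset 5 only).
#' @return An object of class `generation_config`.
#' @export
generation_config <- function(dataset_id = 1,
                              n_controls = 250, n_patients = 250,
                              template_shape = c(32, 32, 32),
                              template_seed = 0,
                              shared_radius_range = c(0.2645, 0.2955),
                              specific_radius_range = c(0.09, 0.12),
                              specific_delta_range = c(0.03, 0.06),
                              shared_support = 0.46,
                              specific_support_factor = 1.15,
                              subtype_loci = NULL,
                              comorbid_loci = NULL) {
  if (!dataset_id %in% 1:5) stop("dataset_id must be in 1..5")
  stopifnot(diff(shared_radius_range) > 0, diff(specific_radius_range) > 0,
            specific_delta_range[1] >= 0, diff(specific_delta_range) >= 0)
  n_subtypes <- c(1L, 2L, 3L, 5L, 2L)[dataset_id]
  if (is.null(subtype_loci)) {
    idx <- switch(dataset_id, 1, 1:2, 1:3, 1:5, 1:2)
    subtype_loci <- lapply(idx, function(i) list(.locus_table[i, ]))
  }
  if (dataset_id == 5 && is.null(comorbid_loci))
    comorbid_loci <- list(.locus_table[5, ])
  structure(list(
    dataset_id = as.integer(dataset_id),
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    n_subtypes = n_subtypes,
    template_shape = as.integer(template_shape),
    template_seed = as.integer(template_seed),
    shared_radius_range = shared_radius_range,
    specific_radius_range = specific_radius_range,
    specific_delta_range = specific_delta_range,
    shared_support = shared_support,
    specific_support_factor = specific_support_factor,
    subtype_loci = subtype_loci, comorbid_loci = comorbid_loci),
    class = "generation_config")
}

# voxel coordinate of a unit-ellipsoid locus (4th element, if any, is sign)
locus_voxel <- function(p, shape) {
  semi <- c(0.42, 0.36, 0.38) * shape
  (shape - 1) / 2 + p[1:3] * semi
}

locus_sign <- function(p) if (length(p) >= 4 && p[4] < 0) -1 else 1

# draw one sphere pair: both radii independent U(range)
draw_sphere <- function(center, radius_range, support) {
  r <- runif(2, radius_range[1], radius_range[2])
  sphere_deformation(center, r_ref = r[1], r_tar = r[2], r_support = support)
}

shared_sphere_for <- function(config) {
  S <- min(config$template_shape)
  draw_sphere((config$template_shape - 1) / 2,
              config$shared_radius_range * S, config$shared_support * S)
}

# each locus has a fixed direction: an expansion locus always expands
# (r_tar > r_ref) and a compression locus always compresses; per-subject
# magnitudes vary uniformly over the configured radius-difference interval
specific_spheres_for <- function(config, loci) {
  S <- min(config$template_shape)
  lapply(loci, function(p) {
    r0 <- runif(1, config$specific_radius_range[1] * S,
                config$specific_radius_range[2] * S)
    delta <- runif(1, config$specific_delta_range[1] * S,
                   config$specific_delta_range[2] * S)
    sphere_deformation(locus_voxel(p, config$template_shape),
                       r_ref = r0, r_tar = r0 + locus_sign(p) * delta,
                       r_support = config$specific_support_factor *
                         (max(config$specific_radius_range) +
                          max(config$specific_delta_range)) * S)
  })
}

# loci (unit-ellipsoid coords) receiving focal effects for one subject
loci_for_subject <- function(config, group, subtype) {
  if (group == "control") return(list())
  loci <- list()
  if (config$dataset_id == 5) {
    if (group %in% c("disorder1", "disorder1+2"))
      loci <- c(loci, config$subtype_loci[[1]])
    if (group %in% c("disorder2", "disorder1+2"))
      loci <- c(loci, config$subtype_loci[[2]])
    loci <- c(loci, config$comorbid_loci)
  } else {
    if (is.na(subtype) || subtype < 1 || subtype > config$n_subtypes)
      stop("unknown subtype for dataset ", config$dataset_id)
    loci <- config$subtype_loci[[subtype]]
  }
  loci
}

#' Sample one synthetic subject
#'
#' Draws a shared whole-brain sphere pair (all subjects) and, for patients,
#' the focal sphere pairs of their subtype or disorder group, composes the
#' displacement fields, and warps the template. Ground-truth magnitudes are
#' recorded as absolute diameter differences `|2 r_tar - 2 r_ref|`.
#'
#' @param group `"control"`, `"patient"` (datasets 1-4) or one of
#'   `"disorder1"`, `"disorder2"`, `"disorder1+2"` (dataset 5).
#' @param subtype integer subtype label (datasets 2-4), otherwise `NA`.
#' @param config a [generation_config()].
#' @param template the template volume (rebuilt from `config` if missing).
#' @return List with `volume` (a `template_volume`) and `truth` (one-row
#'   data frame: subject fields plus sphere parameter list-columns).
#' @export
sample_subject <- function(group, subtype = NA, config, template = NULL) {
  valid <- if (config$dataset_id == 5)
    c("control", "disorder1", "disorder2", "disorder1+2")
  else c("control", "patient")
  if (!group %in% valid)
    stop("unknown group '", group, "' for dataset ", config$dataset_id)
  if (is.null(template))
    template <- make_template(config$template_shape, config$template_seed)

  shared <- shared_sphere_for(config)
  loci <- if (group == "control") list()
          else loci_for_subject(config, group, subtype)
  specific <- if (length(loci)) specific_spheres_for(config, loci) else list()

  field <- build_field(c(list(shared), specific), config$template_shape)
  vol <- warp(template, field)
  truth <- data.frame(
    subject_id = NA_character_, group = group,
    subtype = if (config$dataset_id == 5) NA_integer_ else as.integer(subtype),
    shared_mag = abs(2 * shared$r_tar - 2 * shared$r_ref),
    specific_mag = if (length(specific))
      sum(vapply(specific, function(s) abs(2 * s$r_tar - 2 * s$r_ref), 0))
    else 0,
    stringsAsFactors = FALSE)
  truth$shared_sphere <- list(shared)
  truth$specific_spheres <- list(specific)
  list(volume = vol, truth = truth)
}

#' Generate a synthetic cohort
#'
#' @param dataset_id design 1-5 (see [generation_config()]).
#' @param n total number of subjects; half controls, half patients. The
#'   patient half must divide evenly over the design's subtypes (or the
#'   three comorbidity groups for dataset 5).
#' @param config optional [generation_config()]; group sizes are overridden
#'   by `n`.
#' @param seed integer master seed; identical `(config, seed)` reproduce the
#'   dataset bitwise.
#' @return An object of class `synthetic_dataset`: `volumes` (voxels x
#'   subjects matrix), `truth` (data frame), `template`, `config`, `seed`.
#' @examples
#' ds <- generate_dataset(2, n = 8, config = generation_config(
#'   2, template_shape = c(16, 16, 16)), seed = 1)
#' table(ds$truth$group, ds$truth$subtype, useNA = "ifany")
#' @export
generate_dataset <- function(dataset_id, n, config = NULL, seed = 0) {
  if (n %% 2 != 0) stop("n must be even (1:1 controls to patients)")
  if (is.null(config)) config <- generation_config(dataset_id)
  if (config$dataset_id != dataset_id)
    stop("config was built for dataset ", config$dataset_id)
  n_pat <- n %/% 2
  config$n_controls <- as.integer(n - n_pat)
  config$n_patients <- as.integer(n_pat)

  if (dataset_id == 5) {
    if (n_pat %% 3 != 0) stop("dataset 5 needs patients divisible by 3")
    groups <- c(rep("control", n - n_pat),
                rep(c("disorder1", "disorder2", "disorder1+2"), each = n_pat / 3))
    subtypes <- rep(NA_integer_, n)
  } else {
    k <- config$n_subtypes
    if (n_pat %% k != 0)
      stop("dataset ", dataset_id, " needs patients divisible by ", k)
    groups <- c(rep("control", n - n_pat), rep("patient", n_pat))
    subtypes <- c(rep(NA_integer_, n - n_pat), rep(seq_len(k), each = n_pat / k))
  }

  template <- make_template(config$template_shape, config$template_seed)
  V <- prod(config$template_shape)
  volumes <- matrix(0, nrow = V, ncol = n)
  rows <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      s <- sample_subject(groups[i], subtypes[i], config, template)
      volumes[, i] <- as.numeric(s$volume$grid)
      s$truth$subject_id <- sprintf("sub-%04d", i)
      rows[[i]] <- s$truth
    }
  })
  truth <- do.call(rbind, rows)
  structure(list(volumes = volumes, truth = truth, template = template,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset %d: %d subjects (%s), %s grid, seed %d\n",
              x$config$dataset_id, ncol(x$volumes),
              paste(names(table(x$truth$group)), table(x$truth$group),
                    sep = "=", collapse = ", "),
              paste(x$config$template_shape, collapse = "x"), x$seed))
  invisible(x)
}

#' Shared-to-specific displacement magnitude ratio
#'
#' Draws `n_probe` synthetic patients and, for each, compares the mean
#' voxelwise displacement norm over the brain mask of the shared field to
#' that of the combined disorder-specific field. The default configuration
#' is calibrated so the average ratio is 2.4, mirroring the relative effect
#' sizes of demographic versus disorder effects in neuroanatomy.
#'
#' @param config a [generation_config()].
#' @param n_probe number of sampled patients (>= 50).
#' @param seed RNG seed.
#' @return Mean ratio (scalar).
#' @export
calibrate_ratio <- function(config = generation_config(), n_probe = 200,
                            seed = 0) {
  if (n_probe < 50) stop("n_probe must be >= 50")
  template <- make_template(config$template_shape, config$template_seed)
  mask <- template$brain_mask
  group <- if (config$dataset_id == 5) "disorder1+2" else "patient"
  subtype <- if (config$dataset_id == 5) NA else 1L
  pairs <- with_seed(seed, vapply(seq_len(n_probe), function(i) {
    shared <- shared_sphere_for(config)
    loci <- loci_for_subject(config, group, subtype)
    specific <- specific_spheres_for(config, loci)
    fs <- build_field(list(shared), config$template_shape)
    fp <- build_field(specific, config$template_shape)
    c(mean_displacement(fs, mask), mean_displacement(fp, mask))
  }, c(0, 0)))
  if (mean(pairs[2, ]) == 0) stop("zero specific displacement")
  # ratio of means: the per-subject ratio is heavy-tailed (specific
  # magnitudes can be arbitrarily close to zero), so its average diverges
  mean(pairs[1, ]) / mean(pairs[2, ])
}

#' Ground-truth magnitude map of one subtype
#'
#' Voxelwise Euclidean norm of the subtype's disorder-specific deformation
#' field evaluated at the nominal effect size (reference radius at the
#' interval midpoint, expansion by the expected absolute radius difference).
#' Serves as the reference image when scoring cluster prototypes.
#'
#' @param config a [generation_config()].
#' @param subtype subtype index (datasets 2-4), or 1/2 selecting the
#'   disorder for dataset 5 (unique loci only).
#' @return 3-D array of displacement magnitudes.
#' @export
ground_truth_subtype_map <- function(config, subtype) {
  if (subtype < 1 || subtype > length(config$subtype_loci))
    stop("no such subtype")
  S <- min(config$template_shape)
  r_mid <- mean(config$specific_radius_range) * S
  d_exp <- mean(config$specific_delta_range) * S
  spheres <- lapply(config$subtype_loci[[subtype]], function(p)
    sphere_deformation(locus_voxel(p, config$template_shape),
                       r_ref = r_mid,
                       r_tar = r_mid + locus_sign(p) * d_exp,
                       r_support = config$specific_support_factor *
                         (max(config$specific_radius_range) +
                          max(config$specific_delta_range)) * S))
  f <- build_field(spheres, config$template_shape)
  array(sqrt(rowSums(unclass(f)^2)), dim = config$template_shape)
}

#' Write / read a synthetic dataset directory
#'
#' One NIfTI volume per subject (`sub-XXXX.nii.gz`), a tab-separated
#' ground-truth table (`truth.tsv`) with subject id, group, subtype, the
#' shared and specific magnitudes and flattened sphere parameters, and a
#' YAML snapshot of the generation configuration.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `read_dataset()` returns a `synthetic_dataset` (sphere parameter
#'   list-columns are not restored; magnitudes and labels are).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shp <- dataset$config$template_shape
  for (i in seq_len(ncol(dataset$volumes)))
    write_volume(array(dataset$volumes[, i], dim = shp),
                 file.path(dir, paste0(dataset$truth$subject_id[i], ".nii.gz")))
  flat <- dataset$truth[c("subject_id", "group", "subtype",
                          "shared_mag", "specific_mag")]
  flat$shared_r_ref <- vapply(dataset$truth$shared_sphere, `[[`, 0, "r_ref")
  flat$shared_r_tar <- vapply(dataset$truth$shared_sphere, `[[`, 0, "r_tar")
  flat$specific_spheres <- vapply(dataset$truth$specific_spheres, function(l)
    paste(vapply(l, function(s)
      paste(signif(c(s$center, s$r_ref, s$r_tar, s$r_support), 8),
            collapse = ","), ""), collapse = ";"), "")
  write.table(flat, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(dataset$config)
  cfg$subtype_loci <- lapply(cfg$subtype_loci, function(l) lapply(l, as.numeric))
  cfg$seed <- dataset$seed
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  seed <- cfg$seed; cfg$seed <- NULL
  cfg$n_subtypes <- NULL
  cfg$subtype_loci <- lapply(cfg$subtype_loci, function(l) lapply(l, unlist))
  if (!is.null(cfg$comorbid_loci))
    cfg$comorbid_loci <- lapply(cfg$comorbid_loci, unlist)
  config <- do.call(generation_config, cfg)
  truth <- read.delim(file.path(dir, "truth.tsv"), sep = "\t",
                      stringsAsFactors = FALSE)
  vols <- vapply(truth$subject_id, function(id)
    as.numeric(RNifti::readNifti(file.path(dir, paste0(id, ".nii.gz")))),
    numeric(prod(config$template_shape)))
  template <- make_template(config$template_shape, config$template_seed)
  structure(list(volumes = unname(vols), truth = truth, template = template,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_dataset")
}
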
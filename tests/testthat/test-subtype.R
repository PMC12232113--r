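test_that("the adjusted Rand index matches its closed form and the oracle", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(adjusted_rand_index(c(0, 1, 0, 1), c(0, 0, 1, 1)), -0.5)
  expect_equal(adjusted_rand_index(1:6, 1:6), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), rep(1, 6)), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("the ARI agrees with an independent implementation on all small partitions", {
  # exhaustive: every pair of partitions of n = 5 objects
  parts <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (p in parts(n - 1))
      for (k in seq_len(max(p) + 1)) out <- c(out, list(c(p, k)))
    out
  }
  p5 <- parts(5)
  for (a in p5) for (b in p5) {
    ref <- mclust::adjustedRandIndex(a, b)
    # the reference is undefined (NaN) for two single-cluster partitions,
    # where perfect agreement is conventionally 1
    if (is.nan(ref)) ref <- 1
    expect_equal(adjusted_rand_index(a, b), ref, tolerance = 1e-12)
  }
  # random larger partitions, n = 8
  for (s in 1:25) {
    a <- with_seed(s, sample(1:3, 8, replace = TRUE))
    b <- with_seed(1000 + s, sample(1:4, 8, replace = TRUE))
    ref <- mclust::adjustedRandIndex(a, b)
    if (!is.nan(ref))
      expect_equal(adjusted_rand_index(a, b), ref, tolerance = 1e-12)
  }
})

test_that("K-means subtyping recovers separated clusters exactly", {
  truth <- rep(1:2, each = 10)
  feats <- with_seed(3, cbind(rnorm(20, mean = rep(c(0, 8), each = 10), sd = 0.3),
                              rnorm(20, sd = 0.3)))
  cl <- cluster_and_score(feats, 2, truth, seed = 1)
  expect_equal(cl$ari, 1)
  expect_equal(cl$feature_matrix_shape, c(20L, 2L))
  expect_setequal(unique(cl$labels), c(0L, 1L))
  expect_error(cluster_and_score(feats[1:3, ], 5, truth[1:3]), "fewer subjects")
  expect_error(cluster_and_score(feats, 1, truth), "k must be")
  # oracle ceiling: clustering on the true per-locus magnitudes is perfect
  mags <- with_seed(4, cbind(c(runif(10, 1, 2), rep(0, 10)),
                             c(rep(0, 10), runif(10, 1, 2))))
  expect_equal(cluster_and_score(mags, 2, truth, seed = 2)$ari, 1)
})

test_that("ensemble feature matrices concatenate member latents in order", {
  ds <- fix_dataset()
  m <- fix_model("cvae")
  ens <- structure(list(models = list(m, m, m), spec = m$spec,
                        final_losses = c(3, 1, 2)),
                   class = "cvae_ensemble")
  fm <- ensemble_feature_matrix(ens, ds, "specific")
  expect_equal(dim(fm), c(16L, 6L))  # 3 models x 2 latents
  single <- t(encode(m, ds$volumes)$mu$specific)
  expect_equal(fm[, 1:2], single)
  expect_equal(fm[, 3:4], single)
  one <- structure(list(models = list(m), spec = m$spec, final_losses = 1),
                   class = "cvae_ensemble")
  expect_equal(ensemble_feature_matrix(one, ds, "specific"), single)
  expect_error(ensemble_feature_matrix(one, ds, "nope"), "feature space")
})

test_that("synthetic twins are exactly zero for shared-only reconstructions", {
  m <- random_model("cvae")
  X <- with_seed(8, matrix(runif(512 * 4), 512, 4))
  groups <- c("control", "control", "patient", "patient")
  tw <- synthetic_twin(m, X, groups)
  # controls: both decodes use shared only -> identically zero map
  expect_true(all(tw[, 1:2] == 0))
  expect_gt(max(abs(tw[, 3:4])), 0)
  expect_error(synthetic_twin(random_model("vae"), X, groups), "contrastive")
})

test_that("comorbid maps isolate one space and reject other model kinds", {
  m <- random_model("comorbid_cvae")
  X <- with_seed(9, matrix(runif(512 * 3), 512, 3))
  enc <- encode(m, X)
  d1map <- comorbid_maps(m, X, "d1")
  # invariant to the d2 and patient-shared codes by construction:
  # recompute after perturbing them through a modified encode
  m2 <- m
  m2$weights$bmu_2 <- m2$weights$bmu_2 + 5   # patient_shared mean shift
  m2$weights$bmu_4 <- m2$weights$bmu_4 - 5   # d2 mean shift
  expect_equal(comorbid_maps(m2, X, "d1"), d1map)
  # zero d1 code gives a zero map
  m3 <- m
  m3$weights$Wmu_3[] <- 0
  m3$weights$bmu_3[] <- 0
  expect_true(all(comorbid_maps(m3, X, "d1") == 0))
  expect_error(comorbid_maps(random_model("cvae"), X, "d1"), "comorbid_cvae")
})

test_that("prototype scoring is exact on ground truth and permutation stable", {
  ds <- fix_dataset(2, n = 8)
  gt <- lapply(1:2, ground_truth_subtype_map, config = ds$config)
  perfect <- neurocvae:::score_prototypes(gt, ds)
  expect_equal(perfect$r, c(1, 1))
  expect_equal(perfect$mean_r, 1)
  swapped <- neurocvae:::score_prototypes(gt[2:1], ds)
  expect_equal(swapped$mean_r, 1)
  expect_equal(swapped$assignment, c(2L, 1L))
})

test_that("VAE prototypes are differences of cluster means and control means", {
  ds <- fix_dataset(2, n = 8)
  pat <- ds$truth$group != "control"
  cl <- list(labels = rep(0L, sum(pat)), k = 1L)
  res <- vae_prototypes(ds, cl)
  manual <- abs(rowMeans(ds$volumes[, pat]) - rowMeans(ds$volumes[, !pat]))
  expect_equal(as.numeric(res$prototypes[[1]]), manual)

  same <- ds
  same$volumes[, pat] <- ds$volumes[, !pat]
  res0 <- vae_prototypes(same, cl)
  expect_true(all(res0$prototypes[[1]] == 0))

  nodata <- ds
  nodata$truth$group[] <- "patient"
  expect_error(vae_prototypes(nodata, cl), "controls")
})

test_that("cvae prototypes localize inside the cluster's twin support", {
  ds <- fix_dataset(2, n = 8)
  m <- fix_model("cvae")
  ens <- structure(list(models = list(m), spec = m$spec, final_losses = 1),
                   class = "cvae_ensemble")
  pat <- ds$truth$group != "control"
  cl <- cluster_and_score(ensemble_feature_matrix(ens, ds$volumes[, pat],
                                                  "specific"),
                          2, ds$truth$subtype[pat], seed = 3)
  res <- cvae_prototypes(ens, ds, cl)
  expect_length(res$prototypes, 2)
  expect_true(all(vapply(res$prototypes, function(p) all(is.finite(p)), TRUE)))
  expect_length(res$r, 2)
})
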
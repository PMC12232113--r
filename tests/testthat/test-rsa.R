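test_that("latent RDMs are Euclidean distances with consistent relabeling", {
  mu <- rbind(c(0, 3), c(0, 4))  # dims x subjects: (0,0) and (3,4)
  d <- latent_rdm(mu)
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))

  mu3 <- with_seed(1, matrix(rnorm(12), 2, 6))
  d3 <- latent_rdm(mu3, labels = paste0("p", 1:6))
  perm <- c(3, 1, 6, 2, 5, 4)
  dp <- latent_rdm(mu3[, perm], labels = paste0("p", 1:6)[perm])
  expect_equal(unname(dp[paste0("p", 1:6), paste0("p", 1:6)]), unname(d3))
  expect_equal(d3, t(d3))
  expect_error(latent_rdm(mu[, 1, drop = FALSE]), "two subjects")

  # identical vectors give zero dissimilarity
  expect_equal(latent_rdm(cbind(c(1, 2), c(1, 2)))[1, 2], 0)
})

test_that("magnitude RDMs are absolute differences, translation invariant", {
  expect_equal(magnitude_rdm(c(1, 4))[1, 2], 3)
  expect_true(all(magnitude_rdm(c(2, 2, 2)) == 0))
  m <- c(0.3, 1.9, 0.7, 1.1)
  expect_equal(unclass(magnitude_rdm(m)), unclass(magnitude_rdm(m + 10)))
})

test_that("the RDM correlation is Kendall tau-b with exact small cases", {
  toy_rdm <- function(v) {
    n <- (1 + sqrt(1 + 8 * length(v))) / 2
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- v
    structure(m + t(m), class = c("rdm", "matrix", "array"))
  }
  a <- toy_rdm(c(1, 2, 3))
  expect_equal(rsa_correlation(a, a), 1)
  expect_equal(rsa_correlation(a, toy_rdm(c(3, 2, 1))), -1)
  # brute-force concordant/discordant count: x = (1,2,3,4), y = (1,3,2,4)
  # disagrees only on the (2,3) position pair: (5 - 1) / 6 = 2/3
  brute_tau <- function(x, y) {
    cd <- outer(x, x, `-`) * outer(y, y, `-`)
    ut <- upper.tri(cd)
    (sum(cd[ut] > 0) - sum(cd[ut] < 0)) / sum(ut)
  }
  expect_equal(brute_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  expect_equal(neurocvae:::kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  # swapped neighbours in the upper triangle of a 4-subject RDM
  expect_equal(rsa_correlation(toy_rdm(c(1, 2, 3, 4, 5, 6)),
                               toy_rdm(c(1, 3, 2, 4, 5, 6))),
               brute_tau(c(1, 2, 3, 4, 5, 6), c(1, 3, 2, 4, 5, 6)))
  expect_warning(r <- rsa_correlation(toy_rdm(c(1, 1, 1)), a), "constant")
  expect_true(is.na(r))
})

test_that("the fast Kendall tau matches the quadratic reference, ties included", {
  ref <- function(x, y) suppressWarnings(cor(x, y, method = "kendall"))
  for (s in 1:5) {
    x <- with_seed(100 + s, sample(1:8, 60, replace = TRUE))  # heavy ties
    y <- with_seed(200 + s, x + sample(0:4, 60, replace = TRUE))
    expect_equal(neurocvae:::kendall_tau_b(x, y), ref(x, y), tolerance = 1e-12)
    u <- with_seed(300 + s, rnorm(200))
    v <- with_seed(400 + s, rnorm(200))
    expect_equal(neurocvae:::kendall_tau_b(u, v), ref(u, v), tolerance = 1e-12)
  }
})

test_that("replacing latents by the true magnitudes recovers tau = 1", {
  mags <- with_seed(6, runif(40, 0.1, 3))
  expect_equal(rsa_correlation(latent_rdm(matrix(mags, 1)),
                               magnitude_rdm(mags)), 1)
})

test_that("Fisher-z t-tests match their closed forms", {
  expect_equal(atanh(0.5), log(3) / 2)
  same <- c(0.2, 0.3, 0.25, 0.28, 0.22)
  r <- fisher_z_ttest(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$df, 8)  # two groups of five
  other <- same + 0.2
  r2 <- fisher_z_ttest(other, same)
  expect_gt(r2$t, 0)
  expect_lt(r2$p, 0.05)
  rp <- fisher_z_ttest(other, same, paired = TRUE)
  expect_equal(rp$df, 4)
  expect_error(fisher_z_ttest(c(1, 0.5), same), "strictly inside")
})

test_that("ensemble RSA averages member taus and respects subject subsets", {
  ds <- fix_dataset()
  m <- fix_model("cvae")
  ens <- structure(list(models = list(m, m), spec = m$spec,
                        final_losses = c(1, 1)),
                   class = "cvae_ensemble")
  single <- ensemble_rsa(m, ds, "shared", "shared")
  dup <- ensemble_rsa(ens, ds, "shared", "shared")
  expect_equal(dup$tau, single$tau)
  expect_length(dup$per_model_taus, 2)

  spec_res <- ensemble_rsa(m, ds, "specific", "specific")
  npat <- sum(ds$truth$group != "control")
  expect_equal(spec_res$n_pairs, npat * (npat - 1) / 2)
  all_res <- ensemble_rsa(m, ds, "specific", "specific",
                          include_controls = TRUE)
  expect_equal(all_res$n_pairs, 16 * 15 / 2)
})

test_that("the RSA pipeline is calibrated: no signal against a permuted truth", {
  ds <- fix_dataset(1, n = 16)
  taus <- vapply(1:8, function(s) {
    m <- random_model("cvae", side = 16, seed = 500 + s, filters = c(2, 3))
    shuffled <- ds
    shuffled$truth$shared_mag <- with_seed(700 + s,
                                           sample(ds$truth$shared_mag))
    ensemble_rsa(m, shuffled, "shared", "shared")$tau
  }, 0)
  expect_lt(abs(mean(taus)), 0.15)
  expect_lt(mean(abs(taus)), 0.25)
})

test_that("variance explained matches its definition and the trivial bounds", {
  ds <- fix_dataset()
  m <- fix_model("cvae")
  rec <- predict(m, ds, type = "reconstruction")
  manual <- 1 - sum((ds$volumes - rec)^2) /
    sum((ds$volumes - mean(ds$volumes))^2)
  expect_equal(variance_explained(m, ds), manual)
  const <- ds
  const$volumes <- matrix(0.5, nrow(ds$volumes), ncol(ds$volumes))
  expect_error(variance_explained(m, const), "constant")
})

test_that("the PCA baseline scores train and transfer sets with one loading", {
  ds <- fix_dataset(1, n = 16)
  pb <- pca_baseline(ds, ds, variance_floor = 0.85)
  expect_equal(pb$tau_train, pb$tau_transfer)
  expect_gte(pb$variance_explained, 0.85)
  expect_gte(pb$n_components, 1)
  expect_error(pca_baseline(ds, ds, variance_floor = 1.5), "variance_floor")
})
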
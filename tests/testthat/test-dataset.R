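test_that("cohort composition follows the dataset designs", {
  ds1 <- fix_dataset(1, n = 16)
  expect_equal(sum(ds1$truth$group == "control"), 8)
  expect_equal(sum(ds1$truth$group == "patient"), 8)

  ds2 <- fix_dataset(2, n = 8)
  expect_equal(as.vector(table(ds2$truth$subtype)), c(2L, 2L))

  ds4 <- fix_dataset(4, n = 20)
  expect_equal(as.vector(table(ds4$truth$subtype)), rep(2L, 5))

  ds5 <- fix_dataset(5, n = 12)
  expect_equal(sort(unique(ds5$truth$group)),
               c("control", "disorder1", "disorder1+2", "disorder2"))
  expect_equal(as.vector(table(ds5$truth$group)), c(6L, 2L, 2L, 2L))

  expect_error(generate_dataset(3, 15), "even")
  expect_error(generate_dataset(3, n = 16,
    config = generation_config(3, template_shape = c(16, 16, 16))),
    "divisible by 3")
})

test_that("controls carry no disorder-specific effect", {
  ds <- fix_dataset(1, n = 16)
  ctrl <- ds$truth$group == "control"
  expect_true(all(ds$truth$specific_mag[ctrl] == 0))
  expect_true(all(lengths(ds$truth$specific_spheres[ctrl]) == 0))
  expect_true(all(ds$truth$specific_mag[!ctrl] > 0))
  expect_true(all(ds$truth$shared_mag >= 0))
})

test_that("specific magnitude is the summed absolute diameter difference", {
  ds <- fix_dataset(5, n = 12)
  i <- which(ds$truth$group == "disorder1+2")[1]
  sph <- ds$truth$specific_spheres[[i]]
  expect_length(sph, 3)  # d1 unique + d2 unique + comorbid locus
  expect_equal(ds$truth$specific_mag[i],
               sum(vapply(sph, function(s) abs(2 * s$r_tar - 2 * s$r_ref), 0)))
})

test_that("identical config and seed reproduce the dataset bitwise", {
  cfg <- generation_config(2, template_shape = c(16, 16, 16))
  a <- generate_dataset(2, 8, cfg, seed = 7)
  b <- generate_dataset(2, 8, cfg, seed = 7)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$truth$shared_mag, b$truth$shared_mag)
  c <- generate_dataset(2, 8, cfg, seed = 8)
  expect_false(identical(a$volumes, c$volumes))
})

test_that("controls and patients share the shared-magnitude distribution", {
  cfg <- generation_config(1, template_shape = c(16, 16, 16))
  ds <- generate_dataset(1, 500, cfg, seed = 21)
  ctrl <- ds$truth$group == "control"
  p <- wilcox.test(ds$truth$shared_mag[ctrl],
                   ds$truth$shared_mag[!ctrl])$p.value
  expect_gt(p, 0.01)
})

test_that("the default generator realizes the 2.4x shared-to-specific ratio", {
  cfg <- generation_config(1, template_shape = c(16, 16, 16))
  r <- calibrate_ratio(cfg, n_probe = 800, seed = 4)
  expect_gt(r, 2.2)
  expect_lt(r, 2.6)
  expect_error(calibrate_ratio(cfg, n_probe = 10), "n_probe")
})

test_that("the ratio is homogeneous in each effect amplitude", {
  base <- generation_config(1, template_shape = c(16, 16, 16))
  w <- diff(base$shared_radius_range)
  mid <- mean(base$shared_radius_range)
  doubled <- generation_config(1, template_shape = c(16, 16, 16),
                               shared_radius_range = mid + c(-1, 1) * w)
  r1 <- calibrate_ratio(base, n_probe = 150, seed = 4)
  r2 <- calibrate_ratio(doubled, n_probe = 150, seed = 4)
  expect_equal(r2 / r1, 2.0, tolerance = 0.1)
  # a stronger focal amplitude strictly lowers the ratio (the support
  # radius grows with the amplitude interval, so the scaling is
  # super-linear rather than exactly 2x)
  focal2 <- generation_config(1, template_shape = c(16, 16, 16),
                              specific_delta_range =
                                2 * base$specific_delta_range)
  r3 <- calibrate_ratio(focal2, n_probe = 150, seed = 4)
  expect_gt(r1 / r3, 2.0)
})

test_that("ground-truth subtype maps localize to their loci", {
  cfg <- generation_config(2, template_shape = c(16, 16, 16),
                           specific_radius_range = c(0.06, 0.08),
                           specific_delta_range = c(0.01, 0.03))
  m1 <- ground_truth_subtype_map(cfg, 1)
  m2 <- ground_truth_subtype_map(cfg, 2)
  expect_true(all(m1 >= 0))
  expect_gt(max(m1), 0)
  # disjoint loci with compact supports: no voxel carries both effects
  expect_equal(sum(m1 * m2), 0)
  # degenerate magnitude interval gives the identity deformation
  cfg0 <- generation_config(1, template_shape = c(16, 16, 16),
                            specific_delta_range = c(0, 0))
  expect_lt(max(ground_truth_subtype_map(cfg0, 1)), 1e-6)
  expect_error(ground_truth_subtype_map(cfg, 5), "subtype")
})

test_that("a dataset survives the directory round trip", {
  ds <- fix_dataset(2, n = 8)
  dir <- tempfile("cohort")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$volumes, ds$volumes, tolerance = 1e-6)
  expect_equal(back$truth$group, ds$truth$group)
  expect_equal(back$truth$shared_mag, ds$truth$shared_mag, tolerance = 1e-7)
  expect_equal(back$config$shared_radius_range, ds$config$shared_radius_range)
  unlink(dir, recursive = TRUE)
})

test_that("unknown groups and subtypes are rejected", {
  cfg <- generation_config(1, template_shape = c(16, 16, 16))
  tpl <- make_template(c(16, 16, 16), 0)
  expect_error(sample_subject("disorder1", NA, cfg, tpl), "unknown group")
  expect_error(sample_subject("patient", 7, cfg, tpl), "subtype")
})
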
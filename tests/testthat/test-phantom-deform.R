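test_that("template generation is deterministic and satisfies its invariants", {
  a <- make_template(c(16, 16, 16), seed = 0)
  b <- make_template(c(16, 16, 16), seed = 0)
  expect_identical(a$grid, b$grid)
  expect_true(all(a$grid >= 0 & a$grid <= 1))
  expect_true(all(is.finite(a$grid)))
  frac <- mean(a$brain_mask)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.80)
  expect_true(all(a$grid[!a$brain_mask] == 0))

  d <- make_template(c(16, 16, 16), seed = 1)
  expect_false(identical(a$grid, d$grid))
  # mask volume stable across seeds (within 10%)
  expect_lt(abs(sum(d$brain_mask) - sum(a$brain_mask)) / sum(a$brain_mask), 0.1)

  expect_error(make_template(c(8, 16, 16)), "shape")
})

test_that("radial displacement has the closed form of the sphere-pair field", {
  sp <- sphere_deformation(c(0, 0, 0), r_ref = 8, r_tar = 10, r_support = 20)
  expect_equal(radial_displacement(c(0, 0, 0), sp), c(0, 0, 0))
  # on the reference surface the displacement maps r_ref onto r_tar
  expect_equal(radial_displacement(c(8, 0, 0), sp), c(2, 0, 0))
  # linear decay: at rho = 14, (20 - 14) / (20 - 8) * 2 = 1
  u <- radial_displacement(c(0, 14, 0), sp)
  expect_equal(sqrt(sum(u^2)), 1.0)
  expect_equal(u, c(0, 1, 0))
  # zero at and beyond the support radius
  expect_equal(radial_displacement(c(0, 0, 20), sp), c(0, 0, 0))
  expect_equal(radial_displacement(c(30, 0, 0), sp), c(0, 0, 0))
  # linear interpolation inside the reference sphere
  expect_equal(radial_displacement(c(4, 0, 0), sp), c(1, 0, 0))
})

test_that("swapping reference and target radii flips every displacement", {
  a <- sphere_deformation(c(5, 5, 5), r_ref = 3, r_tar = 4, r_support = 8)
  b <- sphere_deformation(c(5, 5, 5), r_ref = 4, r_tar = 3, r_support = 8)
  pts <- matrix(runif(60, 0, 12), ncol = 3)
  ua <- radial_displacement(pts, a)
  ub <- radial_displacement(pts, b)
  # expansion becomes compression: every component flips sign
  expect_true(all(sign(ua) == -sign(ub)))
  expect_gt(max(abs(ua)), 0)
})

test_that("sphere parameter validation rejects degenerate geometry", {
  expect_error(sphere_deformation(c(0, 0, 0), -1, 2), "positive")
  expect_error(sphere_deformation(c(0, 0, 0), 3, 4, r_support = 4), "r_support")
  expect_silent(sphere_deformation(c(0, 0, 0), 3, 3))  # identity sphere is legal
})

test_that("field building superposes spheres and handles edge cases", {
  shape <- c(16, 16, 16)
  expect_true(all(build_field(list(), shape) == 0))
  ident <- sphere_deformation(c(8, 8, 8), 3, 3, 6)
  expect_true(all(build_field(list(ident), shape) == 0))

  s1 <- sphere_deformation(c(4, 4, 4), 1.5, 2, 3)
  s2 <- sphere_deformation(c(11, 11, 11), 1.5, 1, 3)
  both <- build_field(list(s1, s2), shape)
  f1 <- build_field(list(s1), shape)
  f2 <- build_field(list(s2), shape)
  # disjoint supports: the sum field equals each field inside its own ball
  nz1 <- rowSums(abs(unclass(f1))) > 0
  nz2 <- rowSums(abs(unclass(f2))) > 0
  expect_false(any(nz1 & nz2))
  expect_equal(unclass(both)[nz1, ], unclass(f1)[nz1, ])
  expect_equal(unclass(both)[nz2, ], unclass(f2)[nz2, ])

  expect_warning(build_field(list(sphere_deformation(c(1, 8, 8), 2, 3, 6)), shape),
                 "clipped")
})

test_that("warping is exact on the identity and on integer shifts", {
  tpl <- make_template(c(16, 16, 16), seed = 2)
  expect_identical(warp(tpl, build_field(list(), tpl$shape))$grid, tpl$grid)

  # integer translation inside a flat region preserves intensities exactly
  flat <- tpl
  flat$grid[] <- 0.5
  flat$brain_mask[] <- TRUE
  shift <- build_field(list(), tpl$shape)
  shift[, 1] <- 2  # uniform +2 voxel x-shift
  w <- warp(flat, shift)
  expect_equal(w$grid[5:16, , ], flat$grid[5:16, , ])

  expect_error(warp(tpl, build_field(list(), c(8, 8, 8))), "shape")
})

test_that("warping is local: untouched regions are bit-identical", {
  tpl <- make_template(c(16, 16, 16), seed = 2)
  sp <- sphere_deformation(c(5, 5, 5), 1.5, 2.5, 4)
  w <- warp(tpl, build_field(list(sp), tpl$shape))
  pts <- as.matrix(expand.grid(0:15, 0:15, 0:15))
  outside <- sqrt(rowSums(sweep(pts, 2, c(5, 5, 5))^2)) > 4 + 1.01
  # margin of one voxel for the interpolation stencil
  expect_identical(w$grid[outside], tpl$grid[outside])
})

test_that("an expansion sphere grows a bright blob", {
  shape <- c(16, 16, 16)
  pts <- as.matrix(expand.grid(0:15, 0:15, 0:15))
  rho <- sqrt(rowSums(sweep(pts, 2, c(8, 8, 8))^2))
  blob <- array(pmax(0, 1 - rho / 4), dim = shape)
  vol <- structure(list(grid = blob, brain_mask = blob > 0, shape = shape,
                        spacing = 1), class = "template_volume")
  f <- build_field(list(sphere_deformation(c(8, 8, 8), 3, 4.2, 7)), shape)
  grown <- warp(vol, f)
  expect_gt(sum(grown$grid > 0.5), sum(blob > 0.5))
})

test_that("mean displacement matches a brute-force average and scales linearly", {
  shape <- c(16, 16, 16)
  f0 <- build_field(list(), shape)
  mask <- rep(TRUE, prod(shape))
  expect_equal(mean_displacement(f0, mask), 0)
  fx <- f0; fx[, 1] <- 1
  expect_equal(mean_displacement(fx, mask), 1.0)
  expect_error(mean_displacement(fx, rep(FALSE, prod(shape))), "mask")

  sp <- sphere_deformation(c(8, 8, 8), 3, 4, 7)
  f <- build_field(list(sp), shape)
  pts <- as.matrix(expand.grid(0:15, 0:15, 0:15))
  ball <- sqrt(rowSums(sweep(pts, 2, c(8, 8, 8))^2)) <= 7
  brute <- mean(sqrt(rowSums(radial_displacement(pts[ball, ], sp)^2)))
  expect_equal(mean_displacement(f, ball), brute)

  # homogeneity of degree 1 in (r_tar - r_ref)
  sp2 <- sphere_deformation(c(8, 8, 8), 3, 6, 7)  # 3x the radius difference
  f2 <- build_field(list(sp2), shape)
  expect_equal(mean_displacement(f2, ball), 3 * mean_displacement(f, ball))
})

test_that("volumes survive a NIfTI round trip", {
  tpl <- make_template(c(16, 16, 16), seed = 3)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(tpl, path)
  back <- read_template(path)
  expect_equal(dim(back$grid), c(16L, 16L, 16L))
  expect_equal(back$grid[back$brain_mask], tpl$grid[back$brain_mask],
               tolerance = 1e-6)
  unlink(path)
})
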
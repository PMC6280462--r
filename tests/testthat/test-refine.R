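organ <- make_ellipsoid_mask(c(9, 8, 10), c(30, 30, 30))

test_that("end-to-end affine patch test: refinement reproduces affine fields", {
  A <- rbind(c(0.02, 0.005, 0), c(-0.004, 0.03, 0.01), c(0.002, 0, 0.015))
  b <- c(1, -0.5, 2)
  dvf <- make_affine_dvf(A, b, c(30, 30, 30))
  out <- refine(dvf, organ)
  err <- abs(out$vectors - dvf$vectors)
  expect_lt(max(err), 1e-6)
})

test_that("a zero initial field refines to zero and outside is untouched", {
  z <- zero_dvf(organ)
  out <- refine(z, organ)
  expect_lt(max(abs(out$vectors)), 1e-10)

  set.seed(21)
  noisy <- displacement_field(array(rnorm(prod(c(30, 30, 30, 3))), c(30, 30, 30, 3)))
  # white-noise boundary motion folds elements; the fold warning is expected
  out2 <- suppressWarnings(refine(noisy, organ))
  outside <- !(organ$voxels > 0.5)
  for (c in 1:3)
    expect_identical(out2$vectors[, , , c][outside], noisy$vectors[, , , c][outside])
})

test_that("scatter_to_grid: linear exactness, constants, pass-through", {
  mesh <- tetrahedralize(extract_surface(organ), 1)
  A <- rbind(c(0.01, 0.02, 0), c(0, -0.01, 0.005), c(0.003, 0, 0.02))
  b <- c(0.3, 1, -0.7)
  nodal <- affine_eval(A, b, mesh$nodes)
  set.seed(3)
  init <- displacement_field(array(rnorm(30^3 * 3), c(30, 30, 30, 3)))
  out <- scatter_to_grid(mesh, nodal, organ, init)
  info <- attr(out, "scatter_info")
  expect_gt(info$n_interior, 0)

  pts <- voxel_centers(organ)
  expected <- affine_eval(A, b, pts)
  inorg <- organ$voxels > 0.5
  for (c in 1:3) {
    comp <- out$vectors[, , , c][inorg]
    expect_lt(max(abs(comp - array(expected[, c], dim(organ$voxels))[inorg])), 1e-10)
    expect_identical(out$vectors[, , , c][!inorg], init$vectors[, , , c][!inorg])
  }

  cstval <- c(1.5, -2, 0.25)
  cst <- matrix(cstval, nrow(mesh$nodes), 3, byrow = TRUE)
  outc <- scatter_to_grid(mesh, cst, organ, init)
  for (c in 1:3)
    expect_true(all(abs(outc$vectors[, , , c][inorg] - cstval[c]) < 1e-12))
})

test_that("scatter rejects a mismatched nodal solution", {
  mesh <- tetrahedralize(extract_surface(organ), 2)
  expect_error(scatter_to_grid(mesh, matrix(0, 3, 3), organ, zero_dvf(organ)),
               "match the mesh")
})

test_that("trigger_check counts discrepant voxels like a direct count", {
  z <- zero_dvf(organ)
  t0 <- trigger_check(z, z, organ)
  expect_equal(t0$fraction_above, 0)
  expect_false(t0$flag)

  two <- z
  inorg <- organ$voxels > 0.5
  v <- two$vectors[, , , 1]; v[inorg] <- 2; two$vectors[, , , 1] <- v
  t2 <- trigger_check(z, two, organ, threshold_mm = 1.5)
  expect_equal(t2$fraction_above, 1)
  expect_true(t2$flag)

  set.seed(8)
  a <- displacement_field(array(rnorm(30^3 * 3), c(30, 30, 30, 3)))
  b <- displacement_field(array(rnorm(30^3 * 3), c(30, 30, 30, 3)))
  tc <- trigger_check(a, b, organ, threshold_mm = 1.5)
  expect_equal(tc$fraction_above,
               trd_fraction_bruteforce(a, b, organ, 1.5), tolerance = 1e-12)
})

test_that("refinement recovers a corrupted interior on a small phantom stage", {
  spec <- small_phantom_spec()
  st <- generate_phantom(spec, stages = 8)[[1]]
  org <- st$organ
  corr <- corrupt_dvf(st$dvf_gt, org, amp_mm = 2.5, corr_len_mm = 6, seed = 7)
  refined <- refine(corr, org)
  interior <- bmdir:::erode6(org$voxels > 0.5)
  err <- function(dvf) {
    dd <- dvf$vectors - st$dvf_gt$vectors
    sqrt(dd[, , , 1]^2 + dd[, , , 2]^2 + dd[, , , 3]^2)[interior]
  }
  expect_lt(stats::median(err(refined)), stats::median(err(corr)))
  expect_lt(stats::quantile(err(refined), 0.95),
            stats::quantile(err(corr), 0.95))
  wt_c <- warp_mask(st$tube_def, corr)
  wt_r <- warp_mask(st$tube_def, refined)
  expect_gt(dice(st$tube, wt_r), dice(st$tube, wt_c))
})

test_that("one-voxel feathering blends the boundary shell", {
  spec <- small_phantom_spec()
  st <- generate_phantom(spec, stages = 6)[[1]]
  org <- st$organ
  corr <- corrupt_dvf(st$dvf_gt, org, amp_mm = 2, corr_len_mm = 6, seed = 2)
  hard <- refine(corr, org)
  soft <- refine(corr, org, refinement_config(feather_voxels = 1))
  shell <- mask_boundary(org)
  expected <- 0.5 * hard$vectors[, , , 1][shell] + 0.5 * corr$vectors[, , , 1][shell]
  expect_equal(soft$vectors[, , , 1][shell], expected, tolerance = 1e-12)
  inner <- bmdir:::erode6(org$voxels > 0.5)
  expect_equal(soft$vectors[, , , 1][inner], hard$vectors[, , , 1][inner])
})
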
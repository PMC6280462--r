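test_that("containers enforce their grid invariants", {
  expect_error(image_volume(array(0, c(4, 4, 4)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(image_volume(array(0, c(1, 4, 4))), "at least 2 voxels")
  expect_error(binary_mask(array(2, c(4, 4, 4))), "0 or 1")
  expect_error(displacement_field(array(NaN, c(4, 4, 4, 3))), "finite")
  a <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 2), c(0, 0, 0))
  b <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 2.1), c(0, 0, 0))
  expect_error(check_same_grid(a, b), "spacing")
  expect_true(check_same_grid(a, a))
})

test_that("voxel centers follow the voxel-centre physical model", {
  v <- image_volume(array(0, c(2, 3, 2)), c(0.5, 2, 1), c(10, -5, 3))
  pts <- voxel_centers(v)
  expect_equal(pts[1, ], c(10, -5, 3))
  expect_equal(pts[2, ], c(10.5, -5, 3))           # x fastest
  expect_equal(pts[nrow(pts), ], c(10.5, -1, 4))
})

test_that("NIfTI round trip preserves voxels, spacing and origin", {
  withr::local_tempdir() -> td
  set.seed(1)
  img <- image_volume(array(rnorm(64), c(4, 4, 4)), c(0.5, 0.7, 2), c(3, -2, 11))
  p <- file.path(td, "img.nii.gz")
  write_volume(img, p)
  r <- read_volume(p, "image")
  expect_equal(r$voxels, img$voxels)
  expect_equal(r$spacing, img$spacing)
  expect_equal(r$origin, img$origin)

  dvf <- displacement_field(array(rnorm(64 * 3), c(4, 4, 4, 3)),
                            c(0.5, 0.7, 2), c(3, -2, 11))
  pd <- file.path(td, "dvf.nii.gz")
  write_volume(dvf, pd)
  rd <- read_volume(pd, "dvf")
  expect_equal(rd$vectors, dvf$vectors)
  expect_equal(rd$spacing, dvf$spacing)

  m <- binary_mask(array(rbinom(64, 1, 0.4), c(4, 4, 4)), c(1, 1, 1))
  pm <- file.path(td, "mask.nii.gz")
  write_volume(m, pm)
  rm_ <- read_volume(pm, "mask")
  expect_equal(rm_$voxels, m$voxels)
})

test_that("axis flips in the file header are normalised on read", {
  withr::local_tempdir() -> td
  set.seed(2)
  arr <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  spacing <- c(1, 0.8, 1.5); origin <- c(2, 1, -4)
  # store the x axis reversed with a negative direction entry
  flipped <- arr[4:1, , ]
  img <- RNifti::asNifti(flipped)
  RNifti::pixdim(img) <- spacing
  m <- diag(4); diag(m)[1:3] <- spacing; m[1:3, 4] <- origin
  m[1, 1] <- -spacing[1]
  m[1, 4] <- origin[1] + spacing[1] * 3    # world-x of stored index 0
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  p <- file.path(td, "flip.nii.gz")
  RNifti::writeNifti(img, p)
  r <- read_volume(p, "image")
  expect_equal(r$voxels, arr)
  expect_equal(r$spacing, spacing)
  expect_equal(r$origin, origin)
})

test_that("non-binary files are rejected as masks and DVFs need 3 components", {
  withr::local_tempdir() -> td
  img <- image_volume(array(2, c(4, 4, 4)))
  p <- file.path(td, "two.nii.gz")
  write_volume(img, p)
  expect_error(read_volume(p, "mask"), "other than 0/1")
  expect_error(read_volume(file.path(td, "absent.nii"), "image"), "exist")
})

test_that("NRRD round trip (raw and gzip) preserves scalars and grid", {
  withr::local_tempdir() -> td
  set.seed(3)
  img <- image_volume(array(rnorm(60), c(3, 4, 5)), c(0.5, 0.5, 2), c(-1, 0, 7))
  for (enc in c("gzip", "raw")) {
    p <- file.path(td, paste0(enc, ".nrrd"))
    bmdir:::.write_nrrd(img, p, encoding = enc)
    r <- read_volume(p, "image")
    expect_equal(r$voxels, img$voxels)
    expect_equal(r$spacing, img$spacing)
    expect_equal(r$origin, img$origin)
  }
})

test_that("landmark CSV round trip", {
  withr::local_tempdir() -> td
  lm <- landmark_set(rbind(c(1, 2, 3), c(4, 5, 6)),
                     rbind(c(1.5, 2, 3), c(4, 6, 6)), labels = c("a", "b"))
  p <- file.path(td, "lm.csv")
  write_landmarks(lm, p)
  r <- read_landmarks(p)
  expect_equal(as.matrix(r[, c("fx", "fy", "fz")]),
               as.matrix(lm[, c("fx", "fy", "fz")]))
  expect_equal(r$label, lm$label)
})

test_that("resampling: constants, identity, and exact ramp reproduction", {
  cst <- image_volume(array(7.5, c(8, 8, 8)), c(1, 1, 1))
  out <- resample(cst, c(0.6, 1.3, 0.9))
  expect_true(all(abs(out$voxels - 7.5) < 1e-12))

  set.seed(4)
  img <- image_volume(array(rnorm(512), c(8, 8, 8)), c(1, 2, 1))
  same <- resample(img, c(1, 2, 1))
  expect_identical(same$voxels, img$voxels)

  # ramp I(x) = x_mm, 2x finer: trilinear reproduces linear fields exactly
  d <- c(8, 8, 8)
  ramp <- image_volume(array(rep(seq(0, 7) * 1.0, times = 64), d), c(1, 1, 1))
  fine <- resample(ramp, c(0.5, 0.5, 0.5))
  pts <- voxel_centers(fine)
  expect_lt(max(abs(fine$voxels - array(pts[, 1], dim(fine$voxels)))), 1e-6)
  expect_error(resample(img, c(100, 100, 100)), "degenerate")
})

test_that("mask resampling rethresholds at 0.5", {
  m <- make_sphere_mask(6, c(24, 24, 24))
  r <- resample(m, c(0.8, 0.8, 0.8))
  expect_s3_class(r, "bmdir_mask")
  expect_true(all(r$voxels %in% c(0, 1)))
  expect_gt(sum(r$voxels), 0)
})

test_that("sample_dvf: constants, voxel centres bit-exact, affine to 1e-9", {
  cst <- displacement_field(array(rep(c(1, 2, 3), each = 4^3), c(4, 4, 4, 3)))
  expect_equal(sample_dvf(cst, rbind(c(0.3, 1.7, 2.2), c(3, 3, 3))),
               rbind(c(1, 2, 3), c(1, 2, 3)))

  set.seed(5)
  dvf <- displacement_field(array(rnorm(4^3 * 3), c(4, 4, 4, 3)),
                            c(0.5, 1, 2), c(1, 1, 1))
  expect_identical(as.numeric(sample_dvf(dvf, rbind(c(1 + 2 * 0.5, 1 + 1, 1 + 2 * 2)))),
                   as.numeric(dvf$vectors[3, 2, 3, ]))

  A <- rbind(c(0.1, -0.2, 0), c(0.05, 0.3, 0.01), c(0, 0.02, -0.15))
  b <- c(1, -4, 2)
  dvfA <- make_affine_dvf(A, b, c(12, 12, 12), c(1, 1.5, 1))
  set.seed(6)
  pts <- cbind(runif(100, 1, 10), runif(100, 1.5, 15), runif(100, 1, 10))
  expect_lt(max(abs(sample_dvf(dvfA, pts) - affine_eval(A, b, pts))), 1e-9)
})

test_that("sample_dvf clamps at the margin and rejects NaN fields", {
  cst <- displacement_field(array(rep(c(1, 2, 3), each = 4^3), c(4, 4, 4, 3)))
  expect_equal(as.numeric(sample_dvf(cst, rbind(c(-5, -5, -5)))), c(1, 2, 3))
  bad <- cst; bad$vectors[1] <- NaN
  expect_error(sample_dvf(bad, rbind(c(1, 1, 1))), "NaN")
})

test_that("warping: zero-field identity, analytic translation, out-of-bounds fill", {
  set.seed(7)
  img <- image_volume(array(rnorm(16^3), c(16, 16, 16)))
  z <- zero_dvf(img)
  expect_equal(warp_image(img, z)$voxels, img$voxels)

  # smooth synthetic image; moving is its analytic translate by t
  d <- c(24, 24, 24)
  f <- function(p) sin(p[, 1] / 3) * cos(p[, 2] / 4) + 0.5 * sin(p[, 3] / 5)
  ref <- image_volume(array(f(voxel_centers(image_volume(array(0, d)))), d))
  # fixed x corresponds to moving point x + t, so the pull-back field is u = t
  tr <- c(1.3, -0.7, 2.1)
  mv <- image_volume(array(f(sweep(voxel_centers(ref), 2, tr, "-")), d))
  dvf <- displacement_field(array(rep(tr, each = prod(d)), c(d, 3)))
  w <- warp_image(mv, dvf)
  core <- 5:20
  expect_lt(max(abs(w$voxels[core, core, core] - ref$voxels[core, core, core])),
            0.05)

  far <- displacement_field(array(rep(c(1000, 0, 0), each = prod(d)), c(d, 3)))
  expect_true(all(warp_image(mv, far, fill = -9)$voxels == -9))
})

test_that("warp agrees with an independently written trilinear interpolator", {
  set.seed(8)
  d <- c(10, 10, 10)
  mv <- image_volume(array(rnorm(prod(d)), d), c(1, 1.2, 0.8))
  dvf <- displacement_field(array(rnorm(prod(d) * 3, sd = 0.7), c(d, 3)),
                            c(1, 1.2, 0.8))
  w <- warp_image(mv, dvf, fill = 0)
  pts <- voxel_centers(dvf)
  for (lin in sample(prod(d), 25)) {
    u <- c(dvf$vectors[lin], dvf$vectors[lin + prod(d)],
           dvf$vectors[lin + 2 * prod(d)])
    expect_equal(w$voxels[lin], trilinear_bruteforce(mv, pts[lin, ] + u),
                 tolerance = 1e-12)
  }
})

test_that("mask warping: identity, lattice translation, half-voxel cube", {
  cube <- binary_mask(array(0, c(16, 16, 16)))
  cube$voxels[4:13, 4:13, 4:13] <- 1
  expect_equal(warp_mask(cube, zero_dvf(cube))$voxels, cube$voxels)

  shift <- displacement_field(array(rep(c(2, 0, -1), each = 16^3), c(16, 16, 16, 3)))
  w <- warp_mask(cube, shift)
  expect_equal(w$voxels[2:11, 4:13, 5:14], cube$voxels[4:13, 4:13, 4:13])
  expect_equal(sum(w$voxels), 1000)

  half <- displacement_field(array(rep(c(0.5, 0, 0), each = 16^3), c(16, 16, 16, 3)))
  wh <- warp_mask(cube, half)
  expect_lte(abs(sum(wh$voxels) - 1000), 10 * 10)   # within one voxel layer
})
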
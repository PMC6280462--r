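test_that("Dice: identity, disjoint, half-overlap, symmetry, empty contract", {
  a <- binary_mask(array(0, c(8, 8, 8)))
  a$voxels[2:5, 2:5, 2:5] <- 1
  expect_equal(dice(a, a), 1)

  b <- binary_mask(array(0, c(8, 8, 8)))
  b$voxels[6:7, 6:7, 6:7] <- 1
  expect_equal(dice(a, b), 0)

  # two 4x4x4 cubes overlapping in a 2x4x4 slab: 2*32 / (64+64) = 0.5
  c1 <- binary_mask(array(0, c(10, 10, 10)))
  c1$voxels[2:5, 2:5, 2:5] <- 1
  c2 <- binary_mask(array(0, c(10, 10, 10)))
  c2$voxels[4:7, 2:5, 2:5] <- 1
  expect_equal(dice(c1, c2), 0.5)
  expect_equal(dice(c2, c1), dice(c1, c2))

  e <- binary_mask(array(0, c(8, 8, 8)))
  expect_error(dice(e, e), "empty")
})

test_that("surface distances: identity and two isolated voxels", {
  a <- binary_mask(array(0, c(12, 12, 12)))
  a$voxels[3:8, 3:8, 3:8] <- 1
  sd0 <- surface_distances(a, a)
  expect_equal(sd0$hausdorff_mm, 0)
  expect_equal(sd0$mean_surface_distance_mm, 0)

  # single voxels 3 voxels apart along x at 0.5 mm spacing -> 1.5 mm
  p <- binary_mask(array(0, c(12, 12, 12)), spacing = c(0.5, 1, 1))
  q <- p
  p$voxels[4, 6, 6] <- 1
  q$voxels[7, 6, 6] <- 1
  sd1 <- surface_distances(p, q)
  expect_equal(sd1$hausdorff_mm, 1.5)
  expect_equal(sd1$mean_surface_distance_mm, 1.5)
  expect_error(surface_distances(p, binary_mask(array(0, c(12, 12, 12)),
                                                spacing = c(0.5, 1, 1))),
               "nonempty")
})

test_that("surface distances match the exhaustive pairwise oracle", {
  set.seed(42)
  for (trial in 1:10) {
    a <- random_blob_mask(spacing = c(0.7, 1, 1.4))
    b <- random_blob_mask(spacing = c(0.7, 1, 1.4))
    got <- surface_distances(a, b)
    want <- surface_distances_bruteforce(a, b)
    expect_equal(got$hausdorff_mm, want$hausdorff_mm, tolerance = 1e-9)
    expect_equal(got$mean_surface_distance_mm, want$mean_surface_distance_mm,
                 tolerance = 1e-9)
  }
})

test_that("surface distances are symmetric and bounded by Hausdorff", {
  set.seed(11)
  a <- random_blob_mask(); b <- random_blob_mask()
  s1 <- surface_distances(a, b); s2 <- surface_distances(b, a)
  expect_equal(s1$hausdorff_mm, s2$hausdorff_mm)
  expect_equal(s1$mean_surface_distance_mm, s2$mean_surface_distance_mm)
  expect_gte(s1$hausdorff_mm, s1$mean_surface_distance_mm)
  expect_gte(s1$mean_surface_distance_mm, 0)
})

test_that("Jacobian map: zero field, translation, uniform dilation", {
  d <- c(12, 12, 12)
  z <- displacement_field(array(0, c(d, 3)), c(0.8, 1, 1.3))
  jz <- jacobian_map(z)
  expect_true(all(jz$map$voxels == 1))

  tr <- displacement_field(array(rep(c(4, -2, 1), each = prod(d)), c(d, 3)))
  expect_true(all(abs(jacobian_map(tr)$map$voxels - 1) < 1e-12))

  # u = 0.1 x componentwise: J = 1.1^3 everywhere, border stencils included
  A <- diag(c(0.1, 0.1, 0.1))
  dil <- make_affine_dvf(A, c(0, 0, 0), d, spacing = c(1, 0.5, 2))
  jd <- jacobian_map(dil)
  expect_lt(max(abs(jd$map$voxels - 1.331)), 1e-9)
  expect_equal(jd$mean, 1.331, tolerance = 1e-12)
})

test_that("Jacobian is invariant when a constant translation is added", {
  set.seed(9)
  d <- c(10, 10, 10)
  v <- array(rnorm(prod(d) * 3, sd = 0.3), c(d, 3))
  u1 <- displacement_field(v)
  v2 <- v
  for (c in 1:3) v2[, , , c] <- v2[, , , c] + c(5, -3, 2)[c]
  u2 <- displacement_field(v2)
  expect_equal(jacobian_map(u1)$map$voxels, jacobian_map(u2)$map$voxels,
               tolerance = 1e-12)
})

test_that("TRD: identical, constant offset, histogram equals direct counting", {
  d <- c(14, 14, 14)
  m <- make_sphere_mask(4, d)
  z <- zero_dvf(m)
  t0 <- trd(z, z, m)
  expect_true(all(t0$values == 0))
  expect_true(all(t0$fractions_above == 0))

  off <- displacement_field(array(rep(c(3, 0, 0), each = prod(d)), c(d, 3)))
  t3 <- trd(off, z, m, thresholds_mm = c(1.5, 2, 4))
  expect_true(all(abs(t3$values - 3) < 1e-12))
  expect_equal(unname(t3$fractions_above), c(1, 1, 0))

  set.seed(12)
  a <- displacement_field(array(rnorm(prod(d) * 3), c(d, 3)))
  b <- displacement_field(array(rnorm(prod(d) * 3), c(d, 3)))
  tt <- trd(a, b, m, thresholds_mm = c(1, 2))
  expect_equal(unname(tt$fractions_above[1]),
               trd_fraction_bruteforce(a, b, m, 1), tolerance = 1e-12)
  expect_equal(unname(tt$fractions_above[2]),
               trd_fraction_bruteforce(a, b, m, 2), tolerance = 1e-12)
  # cumulative histogram is non-increasing in the threshold
  expect_true(all(diff(tt$histogram$fraction_above) <= 0))
})

test_that("TRE: constructed correspondence, zero field, affine consistency", {
  d <- c(16, 16, 16)
  fixed <- rbind(c(4, 5, 6), c(8, 7, 9), c(10, 11, 5))
  shift <- c(1.2, -0.8, 0.5)
  dvf <- displacement_field(array(rep(shift, each = prod(d)), c(d, 3)))
  lm <- landmark_set(fixed, sweep(fixed, 2, shift, "+"))
  t0 <- tre(lm, dvf)
  expect_lt(max(t0$per_landmark$tre_mm), 1e-12)

  z <- displacement_field(array(0, c(d, 3)))
  tz <- tre(lm, z)
  expect_equal(tz$per_landmark$tre_mm, rep(sqrt(sum(shift^2)), 3))

  A <- rbind(c(0.05, 0.01, 0), c(0, -0.03, 0.02), c(0.01, 0, 0.04))
  b <- c(0.5, 1, -1)
  dvfA <- make_affine_dvf(A, b, d)
  lmA <- landmark_set(fixed, fixed + affine_eval(A, b, fixed))
  tA <- tre(lmA, dvfA)
  expect_lt(max(tA$per_landmark$tre_mm), 1e-6)

  out <- landmark_set(rbind(c(100, 0, 0)), rbind(c(100, 0, 0)))
  expect_error(tre(out, dvfA), "outside")
})

test_that("metrics_report assembles the battery and tidies to a table", {
  m <- make_sphere_mask(4, c(14, 14, 14))
  z <- zero_dvf(m)
  lm <- landmark_set(rbind(c(6.5, 6.5, 6.5)), rbind(c(6.5, 6.5, 6.5)))
  rep_ <- metrics_report(structure_ref = m, structure_warped = m,
                         dvf = z, organ = m, dvf_compare = z, landmarks = lm)
  expect_equal(rep_$dsc, 1)
  expect_equal(rep_$hausdorff_mm, 0)
  expect_equal(rep_$jacobian$mean, 1)
  expect_equal(rep_$tre$mean, 0)
  td <- tidy(rep_)
  expect_true(all(c("dsc", "jacobian_mean", "tre_mean_mm") %in% td$metric))
})
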
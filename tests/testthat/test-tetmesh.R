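cube_surface <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
               c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
               c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, tri)
}

test_that("unit cube tetrahedralises to exactly unit volume", {
  s <- cube_surface()
  m <- tetrahedralize(s, 0.02)
  expect_lt(abs(sum(tet_volumes(m)) - 1), 1e-6)
  expect_true(all(tet_volumes(m) > 0))
  expect_lte(mean(tet_volumes(m)), 0.02)
})

test_that("sphere mesh volume matches the divergence-theorem volume of its surface", {
  msk <- make_sphere_mask(9, c(28, 28, 28))
  s <- extract_surface(msk)
  vol_surface <- surface_volume(s)         # oracle: volume of the input surface
  m <- tetrahedralize(s, 1)
  expect_lt(abs(sum(tet_volumes(m)) / vol_surface - 1), 0.03)
})

test_that("volume conservation against voxel counting and the sizing rule", {
  msk <- make_ellipsoid_mask(c(9, 8, 10), c(30, 30, 30))
  s <- extract_surface(msk)
  m <- tetrahedralize(s, prod(msk$spacing))
  mask_vol <- sum(msk$voxels) * prod(msk$spacing)
  expect_lt(abs(sum(tet_volumes(m)) / mask_vol - 1), 0.02)
  expect_lte(mean(tet_volumes(m)), prod(msk$spacing))   # sub-voxel elements
})

test_that("a target volume larger than the organ still yields a valid mesh", {
  s <- cube_surface()
  m <- tetrahedralize(s, 1e6)
  expect_gte(nrow(m$tets), 1)
  expect_true(all(tet_volumes(m) > 0))
  expect_lt(abs(sum(tet_volumes(m)) - 1), 1e-6)
})

test_that("surface nodes of the mesh lie on the input surface", {
  msk <- make_sphere_mask(8, c(26, 26, 26))
  s <- extract_surface(msk)
  m <- tetrahedralize(s, 1)
  sn <- m$nodes[m$surface_node_ids, , drop = FALSE]
  set.seed(17)
  sn <- sn[sample(nrow(sn), 150), , drop = FALSE]
  d <- point_to_surface_distance(sn, s)
  expect_lt(max(d), 0.5 * max(msk$spacing))
})

test_that("regular tetrahedron hits the closed-form quality values", {
  p <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  m <- tet_mesh(p, matrix(c(1, 2, 3, 4), 1), 1:4)
  if (tet_volumes(m) < 0) m <- tet_mesh(p, matrix(c(1, 2, 4, 3), 1), 1:4)
  q <- quality_metrics(m)
  expect_equal(q$radius_ratio, 1, tolerance = 1e-9)
  expect_equal(q$edge_ratio, 1, tolerance = 1e-9)
  expect_equal(q$volume_edge, 1, tolerance = 1e-9)
  expect_equal(q$aspect_ratio, 1, tolerance = 1e-9)
  expect_equal(q$min_dihedral_deg, 70.52878, tolerance = 1e-6)
  expect_equal(q$max_dihedral_deg, 70.52878, tolerance = 1e-6)
})

test_that("degenerate coplanar tet: zero volume and zero radius ratio", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  m <- tet_mesh(p, matrix(c(1, 2, 3, 4), 1), 1:4)
  q <- quality_metrics(m)
  expect_equal(q$volume, 0)
  expect_equal(q$radius_ratio, 0)
})

test_that("quality measures are invariant under rigid motion", {
  msk <- make_sphere_mask(6, c(22, 22, 22))
  m <- tetrahedralize(extract_surface(msk, smoothing_iters = 4), 2)
  q0 <- quality_metrics(m)
  set.seed(99)
  R <- random_rotation(); t <- c(5, -3, 12)
  m2 <- m
  m2$nodes <- sweep(m$nodes %*% t(R), 2, t, "+")
  q1 <- quality_metrics(m2)
  for (col in c("volume", "radius_ratio", "edge_ratio", "min_dihedral_deg",
                "max_dihedral_deg", "volume_edge", "aspect_ratio"))
    expect_equal(q1[[col]], q0[[col]], tolerance = 1e-9)
})

test_that("organ meshes are positively oriented everywhere", {
  msk <- make_ellipsoid_mask(c(7, 6, 8), c(26, 26, 26))
  m <- tetrahedralize(extract_surface(msk), 1)
  expect_true(all(tet_volumes(m) > 0))
})

test_that("feature nodes: centroid reuse, vertex idempotence, interior insertion", {
  s <- cube_surface()
  ctr <- bmdir:::.surface_centroid(s)$centroid
  s1 <- insert_feature_nodes(s, rbind(ctr))
  m1 <- tetrahedralize(s1, 0.05)
  id <- attr(m1, "feature_node_ids")
  expect_lt(max(abs(m1$nodes[id, ] - ctr)), 1e-6)

  s2 <- insert_feature_nodes(s, s$vertices[3, , drop = FALSE])
  m2 <- tetrahedralize(s2, 0.05)
  m_plain <- tetrahedralize(s, 0.05)
  expect_equal(nrow(m2$nodes), nrow(m_plain$nodes))   # no duplicate node

  set.seed(31)
  pts <- matrix(runif(30, 0.15, 0.85), 10, 3)
  s3 <- insert_feature_nodes(s, pts)
  m3 <- tetrahedralize(s3, 0.05)
  ids <- attr(m3, "feature_node_ids")
  expect_equal(nrow(rbind(pts)), length(ids))
  expect_lt(max(abs(m3$nodes[ids, ] - pts)), 1e-6)
  expect_true(all(tet_volumes(m3) > 0))
  expect_error(tetrahedralize(insert_feature_nodes(s, rbind(c(5, 5, 5))), 0.05),
               "outside")
})

test_that("mesh exports write valid text decks", {
  withr::local_tempdir() -> td
  m <- tetrahedralize(cube_surface(), 0.05)
  vtk <- file.path(td, "m.vtk"); inp <- file.path(td, "m.inp")
  write_tetmesh_vtk(m, vtk)
  bc <- matrix(0, length(m$surface_node_ids), 3)
  write_abaqus_inp(m, inp, dirichlet = bc)
  expect_true(any(grepl("CELL_TYPES", readLines(vtk))))
  li <- readLines(inp)
  expect_true(any(grepl("C3D4", li)))
  expect_true(any(grepl("NSET=SURFACE", li)))
  expect_true(any(grepl("\\*BOUNDARY", li)))
})
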
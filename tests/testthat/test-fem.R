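regular_tet_mesh <- function() {
  p <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  m <- tet_mesh(p, matrix(c(1, 2, 3, 4), 1), 1:4)
  if (tet_volumes(m) < 0) m <- tet_mesh(p, matrix(c(1, 2, 4, 3), 1), 1:4)
  m
}

# pipeline-generated organ mesh, built once and shared across tests
pipeline_mesh <- local({
  msk <- make_sphere_mask(8, c(26, 26, 26))
  tetrahedralize(extract_surface(msk, smoothing_iters = 5), 2)
})

# a genuinely coarse ball mesh (a few hundred nodes) for dense linear-algebra
# oracles
coarse_ball_mesh <- local({
  ico <- bmdir:::.icosphere(1)
  s <- surface_mesh(ico$vertices * 8, ico$triangles)
  tetrahedralize(s, 1e6)
})

test_that("material constants map to the Lame parameters", {
  m <- elastic_material(0.27, 0.40)
  expect_equal(m$lambda, 0.27 * 0.40 / (1.4 * 0.2))
  expect_equal(m$mu, 0.27 / 2.8)
  expect_error(elastic_material(-1, 0.4), "positive")
  expect_error(elastic_material(1, 0.5), "Poisson")
})

test_that("a fully constrained element yields an empty reduced system", {
  mesh <- regular_tet_mesh()
  bc <- matrix(c(0.1, 0, 0, 0, 0.2, 0, 0, 0, 0.3, 0.1, 0.1, 0.1), 4, 3,
               byrow = TRUE)
  model <- elastic_model(mesh, elastic_material(), dirichlet_ids = 1:4,
                         dirichlet_disp = bc)
  sys <- assemble(model)
  expect_length(sys$free_dofs, 0)
  sol <- solve(model)
  expect_equal(sol$displacement, bc)
})

test_that("the reduced stiffness is symmetric positive-definite", {
  mesh <- coarse_ball_mesh
  model <- elastic_model(mesh, elastic_material(),
                         dirichlet_disp = matrix(0, length(mesh$surface_node_ids), 3))
  sys <- assemble(model)
  K <- as.matrix(sys$K_ff)
  expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("global stiffness is linear in Young's modulus", {
  mesh <- regular_tet_mesh()
  mesh$surface_node_ids <- 1L          # leave nodes 2:4 free
  mk <- function(E) {
    m <- elastic_model(mesh, elastic_material(E, 0.4), dirichlet_ids = 1L,
                       dirichlet_disp = matrix(0, 1, 3))
    assemble(m)
  }
  s1 <- mk(0.27); s2 <- mk(0.54)
  expect_equal(as.matrix(s2$K_ff), 2 * as.matrix(s1$K_ff), tolerance = 1e-12)
})

test_that("zero and rigid-translation boundary conditions reproduce exactly", {
  mesh <- pipeline_mesh
  n_s <- length(mesh$surface_node_ids)
  z <- solve(elastic_model(mesh, dirichlet_disp = matrix(0, n_s, 3)))
  expect_lt(max(abs(z$displacement)), 1e-12)
  expect_true(all(abs(z$tet_jacobian - 1) < 1e-12))

  t_vec <- c(2, -1, 0.5)
  tr <- solve(elastic_model(mesh,
                            dirichlet_disp = matrix(t_vec, n_s, 3, byrow = TRUE)))
  expect_lt(max(abs(sweep(tr$displacement, 2, t_vec))), 1e-8)
})

test_that("affine patch test: interior nodes reproduce the affine field", {
  mesh <- pipeline_mesh
  A <- rbind(c(0.03, 0.01, -0.005), c(0.002, -0.02, 0.01), c(0, 0.015, 0.025))
  b <- c(0.5, -1, 2)
  bc <- affine_eval(A, b, mesh$nodes[mesh$surface_node_ids, , drop = FALSE])
  sol <- solve(elastic_model(mesh, dirichlet_disp = bc))
  expected <- affine_eval(A, b, mesh$nodes)
  rel <- max(abs(sol$displacement - expected)) / max(abs(expected))
  expect_lt(rel, 1e-8)
})

test_that("Young's modulus cancels under full-surface Dirichlet conditions", {
  mesh <- coarse_ball_mesh
  sn <- mesh$nodes[mesh$surface_node_ids, , drop = FALSE]
  ctr <- colMeans(mesh$nodes)
  bc <- push_displacement(sn, ctr + c(0, 0, -14), 6, 1.5)
  sols <- lapply(c(0.027, 0.27, 2.7), function(E)
    solve(elastic_model(mesh, elastic_material(E, 0.40), dirichlet_disp = bc)))
  scale <- max(abs(sols[[2]]$displacement))
  expect_lt(max(abs(sols[[1]]$displacement - sols[[2]]$displacement)) / scale, 1e-8)
  expect_lt(max(abs(sols[[3]]$displacement - sols[[2]]$displacement)) / scale, 1e-8)
  # the Poisson ratio does not cancel
  s45 <- solve(elastic_model(mesh, elastic_material(0.27, 0.45),
                             dirichlet_disp = bc))
  expect_gt(max(abs(s45$displacement - sols[[2]]$displacement)), 1e-6)
})

test_that("scale_invariance_check reports the E/nu sensitivities", {
  mesh <- coarse_ball_mesh
  sn <- mesh$nodes[mesh$surface_node_ids, , drop = FALSE]
  ctr <- colMeans(mesh$nodes)
  bc <- push_displacement(sn, ctr + c(0, 0, -14), 6, 1.5)
  model <- elastic_model(mesh, dirichlet_disp = bc)
  rep_ <- scale_invariance_check(model, e_factors = c(0.1, 10),
                                 nu_values = 0.45)
  e_rows <- rep_[rep_$parameter == "E_factor", ]
  expect_true(all(e_rows$max_abs_diff_mm < 1e-8 * max(abs(bc))))
  expect_gt(rep_$max_abs_diff_mm[rep_$parameter == "nu"], 0)
})

test_that("solution is equivariant under rigid rotation of the whole problem", {
  mesh <- coarse_ball_mesh
  sn_idx <- mesh$surface_node_ids
  ctr <- colMeans(mesh$nodes)
  bc <- push_displacement(mesh$nodes[sn_idx, , drop = FALSE],
                          ctr + c(0, 0, -14), 6, 1.5)
  sol <- solve(elastic_model(mesh, dirichlet_disp = bc))
  set.seed(123)
  R <- random_rotation()
  mesh_r <- mesh
  mesh_r$nodes <- mesh$nodes %*% t(R)
  sol_r <- solve(elastic_model(mesh_r, dirichlet_disp = bc %*% t(R)))
  expect_lt(max(abs(sol_r$displacement - sol$displacement %*% t(R))) /
              max(abs(sol$displacement)), 1e-8)
})

test_that("solution is invariant to node relabelling", {
  mesh <- coarse_ball_mesh
  sn_idx <- mesh$surface_node_ids
  bc <- affine_eval(diag(c(0.02, -0.01, 0.03)), c(0, 1, 0),
                    mesh$nodes[sn_idx, , drop = FALSE])
  sol <- solve(elastic_model(mesh, dirichlet_disp = bc))
  set.seed(5)
  perm <- sample(nrow(mesh$nodes))          # new id of old node i is perm[i]
  mesh_p <- tet_mesh(mesh$nodes[order(perm), , drop = FALSE],
                     matrix(perm[mesh$tets], ncol = 4),
                     perm[sn_idx])
  sol_p <- solve(elastic_model(mesh_p, dirichlet_disp = bc))
  expect_lt(max(abs(sol_p$displacement[perm[seq_len(nrow(mesh$nodes))], ] -
                    sol$displacement)), 1e-8)
})

test_that("tidy and glance expose the nodal solution", {
  mesh <- regular_tet_mesh()
  bc <- matrix(0.1, 4, 3)
  sol <- solve(elastic_model(mesh, dirichlet_ids = 1:4, dirichlet_disp = bc))
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_true(all(td$on_surface))
  g <- glance(sol)
  expect_equal(g$n_free_dofs, 0)
  expect_equal(g$jacobian_min, 1, tolerance = 1e-12)
})

test_that("degenerate models are rejected", {
  mesh <- regular_tet_mesh()
  expect_error(elastic_model(mesh, dirichlet_ids = 1:2,
                             dirichlet_disp = matrix(0, 2, 3)),
               "every surface node")
  bad <- mesh; bad$tets <- matrix(c(1, 2, 4, 3), 1)  # inverted
  if (tet_volumes(bad) > 0) bad$tets <- matrix(c(1, 2, 3, 4), 1)
  expect_error(elastic_model(bad, dirichlet_ids = 1:4,
                             dirichlet_disp = matrix(0, 4, 3)),
               "inverted")
})
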
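# The refinement pipeline: extract the organ surface, mesh it, drive a
# linear-elastic solve with surface displacements sampled from the initial
# field, and scatter the nodal solution back to the voxel grid inside the
# organ. Outside the organ the initial field passes through untouched.

#' Configuration for biomechanical field refinement
#'
#' @param material an [elastic_material()] (default nu = 0.40,
#'   E = 0.27 MPa, soft-tissue values).
#' @param target_mean_tet_volume_mm3 mean element volume for the mesh;
#'   `NULL` (default) uses the image voxel volume, per the sizing rule that
#'   elements should be slightly smaller than a voxel.
#' @param smoothing_iters surface Taubin smoothing iterations.
#' @param field_sigma mask pre-smoothing sigma in voxels for surface
#'   extraction.
#' @param feather_voxels width (in voxels) of optional linear blending at the
#'   organ boundary between the initial and refined fields; 0 (default) is a
#'   hard switch at the mask.
#' @param solver_tol admissible relative residual of the FEM solve.
#' @param decimate_triangles surface decimation threshold passed to
#'   [tetrahedralize()].
#' @return An object of class `bmdir_refinement_config`.
#' @export
refinement_config <- function(material = elastic_material(),
                              target_mean_tet_volume_mm3 = NULL,
                              smoothing_iters = 10,
                              field_sigma = 1,
                              feather_voxels = 0,
                              solver_tol = 1e-8,
                              decimate_triangles = 6000) {
  stopifnot(inherits(material, "bmdir_material"))
  structure(list(material = material,
                 target_mean_tet_volume_mm3 = target_mean_tet_volume_mm3,
                 smoothing_iters = smoothing_iters,
                 field_sigma = field_sigma,
                 feather_voxels = feather_voxels,
                 solver_tol = solver_tol,
                 decimate_triangles = decimate_triangles),
            class = "bmdir_refinement_config")
}

# voxel -> element interpolation weights for all organ voxels; computed once
# per mesh/grid pair and reusable across solves on the same mesh.
.build_scatter <- function(mesh, organ, bary_tol = -1e-9) {
  d <- vol_dim(organ)
  sp <- organ$spacing; or <- organ$origin
  org <- organ$voxels > 0.5
  vox_lin <- which(org)
  n_org <- length(vox_lin)
  assigned_tet <- integer(prod(d))          # 0 = unassigned
  bary_store <- matrix(0, prod(d), 4)       # only organ rows used

  nod <- mesh$nodes; tt <- mesh$tets
  p1 <- nod[tt[, 1], , drop = FALSE]
  v1 <- nod[tt[, 2], , drop = FALSE] - p1
  v2 <- nod[tt[, 3], , drop = FALSE] - p1
  v3 <- nod[tt[, 4], , drop = FALSE] - p1
  cross <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                u[, 1] * w[, 2] - u[, 2] * w[, 1])
  det <- rowSums(v1 * cross(v2, v3))
  r1 <- cross(v2, v3) / det; r2 <- cross(v3, v1) / det; r3 <- cross(v1, v2) / det
  xmin <- pmin(p1[, 1], p1[, 1] + v1[, 1], p1[, 1] + v2[, 1], p1[, 1] + v3[, 1])
  xmax <- pmax(p1[, 1], p1[, 1] + v1[, 1], p1[, 1] + v2[, 1], p1[, 1] + v3[, 1])
  ymin <- pmin(p1[, 2], p1[, 2] + v1[, 2], p1[, 2] + v2[, 2], p1[, 2] + v3[, 2])
  ymax <- pmax(p1[, 2], p1[, 2] + v1[, 2], p1[, 2] + v2[, 2], p1[, 2] + v3[, 2])
  zmin <- pmin(p1[, 3], p1[, 3] + v1[, 3], p1[, 3] + v2[, 3], p1[, 3] + v3[, 3])
  zmax <- pmax(p1[, 3], p1[, 3] + v1[, 3], p1[, 3] + v2[, 3], p1[, 3] + v3[, 3])
  i0 <- pmax(0L, as.integer(ceiling((xmin - or[1]) / sp[1] - 1e-9)))
  i1 <- pmin(d[1] - 1L, as.integer(floor((xmax - or[1]) / sp[1] + 1e-9)))
  j0 <- pmax(0L, as.integer(ceiling((ymin - or[2]) / sp[2] - 1e-9)))
  j1 <- pmin(d[2] - 1L, as.integer(floor((ymax - or[2]) / sp[2] + 1e-9)))
  k0 <- pmax(0L, as.integer(ceiling((zmin - or[3]) / sp[3] - 1e-9)))
  k1 <- pmin(d[3] - 1L, as.integer(floor((zmax - or[3]) / sp[3] + 1e-9)))

  for (e in seq_len(nrow(tt))) {
    if (i1[e] < i0[e] || j1[e] < j0[e] || k1[e] < k0[e]) next
    is <- i0[e]:i1[e]; js <- j0[e]:j1[e]; ks <- k0[e]:k1[e]
    lin <- as.vector(outer(outer(is + 1L, js * d[1], "+"),
                           ks * (d[1] * d[2]), "+"))
    lin <- lin[org[lin] & assigned_tet[lin] == 0L]
    if (!length(lin)) next
    i <- (lin - 1L) %% d[1]
    j <- ((lin - 1L) %/% d[1]) %% d[2]
    k <- (lin - 1L) %/% (d[1] * d[2])
    px <- or[1] + i * sp[1] - p1[e, 1]
    py <- or[2] + j * sp[2] - p1[e, 2]
    pz <- or[3] + k * sp[3] - p1[e, 3]
    b1 <- r1[e, 1] * px + r1[e, 2] * py + r1[e, 3] * pz
    b2 <- r2[e, 1] * px + r2[e, 2] * py + r2[e, 3] * pz
    b3 <- r3[e, 1] * px + r3[e, 2] * py + r3[e, 3] * pz
    b0 <- 1 - b1 - b2 - b3
    ok <- b0 >= bary_tol & b1 >= bary_tol & b2 >= bary_tol & b3 >= bary_tol
    if (any(ok)) {
      sel <- lin[ok]
      assigned_tet[sel] <- e
      bary_store[sel, ] <- cbind(b0[ok], b1[ok], b2[ok], b3[ok])
    }
  }

  inside <- vox_lin[assigned_tet[vox_lin] > 0L]
  outside <- setdiff(vox_lin, inside)
  fallback_extrap <- integer(0); fallback_node <- integer(0)
  if (length(outside)) {
    # shell voxels inside the mask but outside every element: extrapolate
    # from the best element incident to the nearest node if within one voxel,
    # else take the nearest node's value
    i <- (outside - 1L) %% d[1]
    j <- ((outside - 1L) %/% d[1]) %% d[2]
    k <- (outside - 1L) %/% (d[1] * d[2])
    pts <- cbind(or[1] + i * sp[1], or[2] + j * sp[2], or[3] + k * sp[3])
    nn_id <- integer(length(outside))
    sn <- mesh$nodes
    for (s in seq(1L, length(outside), by = 512L)) {
      en <- min(length(outside), s + 511L)
      d2 <- -2 * tcrossprod(pts[s:en, , drop = FALSE], sn) +
            rowSums(pts[s:en, , drop = FALSE]^2)
      d2 <- sweep(d2, 2L, rowSums(sn^2), "+")
      nn_id[s:en] <- max.col(-d2, ties.method = "first")
    }
    nn_dist <- sqrt(rowSums((pts - sn[nn_id, , drop = FALSE])^2))
    within <- nn_dist <= max(sp)
    incident <- lapply(seq_len(nrow(sn)), function(x) integer(0))
    for (a in 1:4) {
      byn <- split(seq_len(nrow(tt)), tt[, a])
      for (nm in names(byn)) {
        id <- as.integer(nm)
        incident[[id]] <- c(incident[[id]], byn[[nm]])
      }
    }
    for (q in seq_along(outside)) {
      lin <- outside[q]
      cand <- incident[[nn_id[q]]]
      if (within[q] && length(cand)) {
        px <- pts[q, 1] - p1[cand, 1]
        py <- pts[q, 2] - p1[cand, 2]
        pz <- pts[q, 3] - p1[cand, 3]
        b1 <- r1[cand, 1] * px + r1[cand, 2] * py + r1[cand, 3] * pz
        b2 <- r2[cand, 1] * px + r2[cand, 2] * py + r2[cand, 3] * pz
        b3 <- r3[cand, 1] * px + r3[cand, 2] * py + r3[cand, 3] * pz
        b0 <- 1 - b1 - b2 - b3
        best <- which.max(pmin(b0, b1, b2, b3))
        assigned_tet[lin] <- cand[best]
        bary_store[lin, ] <- c(b0[best], b1[best], b2[best], b3[best])
        fallback_extrap <- c(fallback_extrap, lin)
      } else {
        fallback_node <- c(fallback_node, lin)
        assigned_tet[lin] <- -nn_id[q]         # negative marks node fallback
      }
    }
  }
  list(vox_lin = vox_lin, assigned = assigned_tet, bary = bary_store,
       n_interior = length(inside),
       n_extrapolated = length(fallback_extrap),
       n_node_fallback = length(fallback_node))
}

.apply_scatter <- function(sc, mesh, nodal_u, organ, dvf_init) {
  out <- dvf_init$vectors
  d <- vol_dim(organ)
  npl <- prod(d)
  tt <- mesh$tets
  lin <- sc$vox_lin
  a <- sc$assigned[lin]
  pos <- a > 0L
  if (any(pos)) {
    lp <- lin[pos]; te <- a[pos]
    w <- sc$bary[lp, , drop = FALSE]
    for (c in 1:3) {
      vals <- w[, 1] * nodal_u[tt[te, 1], c] + w[, 2] * nodal_u[tt[te, 2], c] +
              w[, 3] * nodal_u[tt[te, 3], c] + w[, 4] * nodal_u[tt[te, 4], c]
      out[lp + (c - 1) * npl] <- vals
    }
  }
  if (any(!pos)) {
    ln <- lin[!pos]; nid <- -a[!pos]
    for (c in 1:3) out[ln + (c - 1) * npl] <- nodal_u[nid, c]
  }
  displacement_field(out, dvf_init$spacing, dvf_init$origin)
}

#' Scatter nodal displacements to the voxel grid inside an organ
#'
#' Each organ voxel center is located in its containing tetrahedron (axis-
#' aligned bounding-box spatial index, barycentric containment with a -1e-9
#' tolerance) and the four nodal vectors are barycentrically interpolated —
#' the scattered linear interpolation of the refinement step. Voxels inside
#' the mask but outside every element are extrapolated from the nearest
#' node's best incident element when within one voxel of the mesh, otherwise
#' they take the nearest node's value; both cases are counted in
#' `attr(, "scatter_info")`. Voxels outside the organ are copied bit-exactly
#' from `dvf_init`.
#'
#' @param mesh a [tet_mesh()].
#' @param nodal_u n_nodes-by-3 matrix of nodal displacements (mm).
#' @param organ the organ [binary_mask()] on the reference grid.
#' @param dvf_init the initial [displacement_field()] (pass-through outside).
#' @return A [displacement_field()].
#' @export
scatter_to_grid <- function(mesh, nodal_u, organ, dvf_init) {
  stopifnot(inherits(mesh, "bmdir_tetmesh"), inherits(organ, "bmdir_mask"),
            inherits(dvf_init, "bmdir_dvf"))
  check_same_grid(organ, dvf_init)
  if (nrow(nodal_u) != nrow(mesh$nodes))
    stop("nodal solution does not match the mesh", call. = FALSE)
  sc <- .build_scatter(mesh, organ)
  out <- .apply_scatter(sc, mesh, nodal_u, organ, dvf_init)
  attr(out, "scatter_info") <- sc[c("n_interior", "n_extrapolated", "n_node_fallback")]
  out
}

#' Biomechanically refine a displacement field inside an organ
#'
#' The full refinement pipeline: organ surface extraction, tetrahedral
#' meshing at sub-voxel mean element volume, surface-node boundary
#' displacements sampled trilinearly from the initial field, linear-elastic
#' solve for the interior nodes, and scattered linear interpolation of the
#' nodal solution back to the organ voxels. Voxels outside the organ keep
#' the initial field unchanged.
#'
#' @param dvf_init initial [displacement_field()] (e.g. from an intensity-
#'   based registration) on the reference grid.
#' @param organ organ [binary_mask()] on the same grid.
#' @param cfg a [refinement_config()].
#' @return The refined [displacement_field()], with pipeline diagnostics in
#'   `attr(, "refine_info")`.
#' @export
refine <- function(dvf_init, organ, cfg = refinement_config()) {
  stopifnot(inherits(dvf_init, "bmdir_dvf"), inherits(organ, "bmdir_mask"),
            inherits(cfg, "bmdir_refinement_config"))
  check_same_grid(dvf_init, organ)
  target <- cfg$target_mean_tet_volume_mm3
  if (is.null(target)) target <- prod(organ$spacing)
  surf <- extract_surface(organ, cfg$smoothing_iters, cfg$field_sigma)
  mesh <- tetrahedralize(surf, target, cfg$decimate_triangles)
  sol <- refine_on_mesh(dvf_init, organ, mesh, cfg)
  sol
}

# refinement given a prebuilt mesh (lets callers reuse mesh/factor/scatter)
refine_on_mesh <- function(dvf_init, organ, mesh, cfg = refinement_config(),
                           cache = NULL) {
  bc <- sample_dvf(dvf_init, mesh$nodes[mesh$surface_node_ids, , drop = FALSE])
  if (is.null(cache)) {
    model <- elastic_model(mesh, cfg$material,
                           dirichlet_ids = mesh$surface_node_ids,
                           dirichlet_disp = bc)
    sol <- solve(model, tol = cfg$solver_tol)
    u <- sol$displacement
    sc <- .build_scatter(mesh, organ)
    info <- list(n_nodes = nrow(mesh$nodes), n_tets = nrow(mesh$tets),
                 residual = sol$residual,
                 n_extrapolated = sc$n_extrapolated,
                 n_node_fallback = sc$n_node_fallback)
  } else {
    u <- cache$solve(bc)
    sc <- cache$scatter
    info <- list(n_nodes = nrow(mesh$nodes), n_tets = nrow(mesh$tets),
                 residual = NA_real_,
                 n_extrapolated = sc$n_extrapolated,
                 n_node_fallback = sc$n_node_fallback)
  }
  out <- .apply_scatter(sc, mesh, u, organ, dvf_init)
  if (cfg$feather_voxels > 0) {
    shell <- mask_boundary(organ)
    w <- 0.5     # one-voxel linear feathering at the mask boundary
    for (c in 1:3) {
      o <- out$vectors[, , , c]; i <- dvf_init$vectors[, , , c]
      o[shell] <- w * o[shell] + (1 - w) * i[shell]
      out$vectors[, , , c] <- o
    }
  }
  attr(out, "refine_info") <- info
  out
}

# reusable solve/scatter closures for repeated refinements on one mesh
.make_refine_cache <- function(mesh, organ, cfg) {
  model0 <- elastic_model(mesh, cfg$material,
                          dirichlet_ids = mesh$surface_node_ids,
                          dirichlet_disp = matrix(0, length(mesh$surface_node_ids), 3))
  sys <- assemble(model0)
  factor <- if (length(sys$free_dofs) <= 2e5)
    Matrix::Cholesky(sys$K_ff, LDL = FALSE) else NULL
  nn <- sys$n_nodes
  solve_fun <- function(bc) {
    u_fixed <- as.numeric(t(bc))
    rhs <- as.numeric(-(sys$K_fb %*% u_fixed))
    u_free <- if (!is.null(factor)) as.numeric(Matrix::solve(factor, rhs))
              else .pcg(sys$K_ff, rhs)
    u <- numeric(3 * nn)
    u[sys$fixed_dofs] <- u_fixed
    u[sys$free_dofs] <- u_free
    matrix(u, ncol = 3, byrow = TRUE)
  }
  list(solve = solve_fun, scatter = .build_scatter(mesh, organ))
}

#' Flag large interior disagreement between two fields
#'
#' Computes the fraction of organ voxels whose vector discrepancy (TRD)
#' between the initial and refined fields exceeds `threshold_mm`, and raises
#' a flag when that fraction passes `flag_fraction` — large silent
#' disagreement inside a feature-poor organ is a cue for manual inspection
#' of the registration.
#'
#' @param dvf_init,dvf_refined fields on the same grid.
#' @param organ organ [binary_mask()].
#' @param threshold_mm TRD cut, default 1.5 mm.
#' @param flag_fraction fraction above the cut that raises the flag.
#' @return A list: `fraction_above`, `flag`, `threshold_mm`, `trd` (the
#'   underlying `bmdir_trd`).
#' @export
trigger_check <- function(dvf_init, dvf_refined, organ, threshold_mm = 1.5,
                          flag_fraction = 0.1) {
  t <- trd(dvf_init, dvf_refined, organ, thresholds_mm = threshold_mm)
  fr <- unname(t$fractions_above[1])
  list(fraction_above = fr, flag = fr > flag_fraction,
       threshold_mm = threshold_mm, trd = t)
}
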
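# Tetrahedral volume meshing of a closed, star-shaped triangulated surface.
# The input triangulation is kept verbatim as the mesh boundary; the interior
# is filled with nested scaled copies of the surface ("onion" layers) joined
# by prism frusta (split face-consistently through their centroids) and an
# innermost fan to the volume centroid. The sum of element volumes therefore
# equals the divergence-theorem volume of the input surface to round-off.
# Overly fine input surfaces are first remeshed by casting icosphere rays
# from the centroid onto the surface (vertices land exactly on it).

#' Construct a tetrahedral mesh
#'
#' @param nodes n-by-3 matrix of node coordinates (mm).
#' @param tets m-by-4 integer matrix of 1-based node indices, positively
#'   oriented (positive signed volume).
#' @param surface_node_ids integer indices of nodes on the boundary surface.
#' @return An object of class `bmdir_tetmesh`.
#' @export
tet_mesh <- function(nodes, tets, surface_node_ids) {
  nodes <- rbind(nodes); tets <- rbind(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L, length(surface_node_ids) >= 1L)
  structure(list(nodes = nodes, tets = tets,
                 surface_node_ids = as.integer(surface_node_ids)),
            class = "bmdir_tetmesh")
}

#' @export
print.bmdir_tetmesh <- function(x, ...) {
  v <- tet_volumes(x)
  cat(sprintf("<bmdir_tetmesh> %d nodes (%d on surface), %d tets, total volume %.1f mm^3, mean tet %.3g mm^3\n",
              nrow(x$nodes), length(x$surface_node_ids), nrow(x$tets),
              sum(v), mean(v)))
  invisible(x)
}

#' Signed volumes of all tetrahedra
#' @param mesh a [tet_mesh()].
#' @return Numeric vector of signed volumes in mm^3.
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tets
  a <- n[t[, 2], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  b <- n[t[, 3], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  d <- n[t[, 4], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

.fix_orientation <- function(tets, nodes) {
  m <- tet_mesh(nodes, tets, 1L)
  v <- tet_volumes(m)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tets
}

# ---- icosphere + ray-cast remeshing ----------------------------------------

.icosphere <- function(subdiv) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  s <- surface_mesh(v / sqrt(rowSums(v^2)), f)
  for (i in seq_len(subdiv)) {
    s <- .subdivide_surface(s)
    s$vertices <- s$vertices / sqrt(rowSums(s$vertices^2))
  }
  s
}

# midpoint 4-split with welded edge midpoints; geometry unchanged
.subdivide_surface <- function(surface) {
  v <- surface$vertices; t <- surface$triangles
  nv <- nrow(v)
  e <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  uk <- unique(key)
  mid_id <- nv + match(key, uk)
  first <- match(uk, key)
  mids <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
  v2 <- rbind(v, mids)
  n <- nrow(t)
  mAB <- mid_id[seq_len(n)]; mBC <- mid_id[n + seq_len(n)]; mCA <- mid_id[2 * n + seq_len(n)]
  t2 <- rbind(cbind(t[, 1], mAB, mCA),
              cbind(mAB, t[, 2], mBC),
              cbind(mCA, mBC, t[, 3]),
              cbind(mAB, mBC, mCA))
  surface_mesh(v2, t2)
}

# volume centroid of a closed surface via the divergence theorem
.surface_centroid <- function(surface) {
  v <- surface$vertices; t <- surface$triangles
  p1 <- v[t[, 1], , drop = FALSE]; p2 <- v[t[, 2], , drop = FALSE]
  p3 <- v[t[, 3], , drop = FALSE]
  vol6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  V <- sum(vol6) / 6
  ctr <- colSums((p1 + p2 + p3) / 4 * vol6) / 6 / V
  list(centroid = ctr, volume = V)
}

.star_shaped <- function(surface, center) {
  v <- surface$vertices; t <- surface$triangles
  p1 <- sweep(v[t[, 1], , drop = FALSE], 2, center)
  p2 <- sweep(v[t[, 2], , drop = FALSE], 2, center)
  p3 <- sweep(v[t[, 3], , drop = FALSE], 2, center)
  vol <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
         p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
         p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  all(vol > 0)
}

# remesh a star-shaped surface by casting icosphere directions from center
.raycast_remesh <- function(surface, center, subdiv) {
  ico <- .icosphere(subdiv)
  D <- ico$vertices                              # unit directions
  v <- surface$vertices; t <- surface$triangles
  nt <- nrow(t)
  # per-triangle inverse of M = [p1-c, p2-c, p3-c] (columns)
  P1 <- sweep(v[t[, 1], , drop = FALSE], 2, center)
  P2 <- sweep(v[t[, 2], , drop = FALSE], 2, center)
  P3 <- sweep(v[t[, 3], , drop = FALSE], 2, center)
  det <- P1[, 1] * (P2[, 2] * P3[, 3] - P2[, 3] * P3[, 2]) -
         P2[, 1] * (P1[, 2] * P3[, 3] - P1[, 3] * P3[, 2]) +
         P3[, 1] * (P1[, 2] * P2[, 3] - P1[, 3] * P2[, 2])
  # rows of M^-1 (adjugate / det); beta = Minv %*% d
  r1 <- cbind(P2[, 2] * P3[, 3] - P2[, 3] * P3[, 2],
              P2[, 3] * P3[, 1] - P2[, 1] * P3[, 3],
              P2[, 1] * P3[, 2] - P2[, 2] * P3[, 1]) / det
  r2 <- cbind(P3[, 2] * P1[, 3] - P3[, 3] * P1[, 2],
              P3[, 3] * P1[, 1] - P3[, 1] * P1[, 3],
              P3[, 1] * P1[, 2] - P3[, 2] * P1[, 1]) / det
  r3 <- cbind(P1[, 2] * P2[, 3] - P1[, 3] * P2[, 2],
              P1[, 3] * P2[, 1] - P1[, 1] * P2[, 3],
              P1[, 1] * P2[, 2] - P1[, 2] * P2[, 1]) / det
  # bucket triangles by direction (azimuth/elevation of their vertex rays)
  # so each icosphere ray only tests nearby triangles
  naz <- 64L; nel <- 32L
  dir_az <- function(p) atan2(p[, 2], p[, 1])
  dir_el <- function(p) asin(pmin(pmax(p[, 3] / sqrt(rowSums(p^2)), -1), 1))
  az <- cbind(dir_az(P1), dir_az(P2), dir_az(P3))
  el <- cbind(dir_el(P1), dir_el(P2), dir_el(P3))
  azb <- matrix(pmin(naz - 1, pmax(0, floor((az + pi) / (2 * pi) * naz))), ncol = 3)
  elb <- matrix(pmin(nel - 1, pmax(0, floor((el + pi / 2) / pi * nel))), ncol = 3)
  a_lo <- pmin(azb[, 1], azb[, 2], azb[, 3]) - 1L
  a_hi <- pmax(azb[, 1], azb[, 2], azb[, 3]) + 1L
  wrap <- (a_hi - a_lo) > naz / 2               # crosses the +-pi seam
  a_lo[wrap] <- 0L; a_hi[wrap] <- naz - 1L
  e_lo <- pmax(0L, pmin(elb[, 1], elb[, 2], elb[, 3]) - 1L)
  e_hi <- pmin(nel - 1L, pmax(elb[, 1], elb[, 2], elb[, 3]) + 1L)
  # triangles whose vertices span polar caps get all azimuths
  polar <- e_lo == 0L | e_hi == nel - 1L
  a_lo[polar] <- 0L; a_hi[polar] <- naz - 1L
  na_bins <- a_hi - a_lo + 1L; ne_bins <- e_hi - e_lo + 1L
  tri_ids <- binc <- vector("list", 0)
  acc_t <- acc_b <- vector("list", max(na_bins) * max(ne_bins))
  q <- 0
  for (da in 0:(max(na_bins) - 1L)) for (de in 0:(max(ne_bins) - 1L)) {
    sel <- which(na_bins > da & ne_bins > de)
    if (!length(sel)) next
    q <- q + 1
    acc_t[[q]] <- sel
    acc_b[[q]] <- ((a_lo[sel] + da) %% naz) * nel + (e_lo[sel] + de)
  }
  tri_by_bin <- split(unlist(acc_t[seq_len(q)]), unlist(acc_b[seq_len(q)]))
  ray_bin <- as.character(
    pmin(naz - 1L, pmax(0L, floor((atan2(D[, 2], D[, 1]) + pi) / (2 * pi) * naz))) * nel +
    pmin(nel - 1L, pmax(0L, floor((asin(pmin(pmax(D[, 3], -1), 1)) + pi / 2) / pi * nel))))
  nr <- nrow(D)
  best_t <- rep(-Inf, nr)
  tol <- -1e-10
  for (s in seq_len(nr)) {
    cand <- tri_by_bin[[ray_bin[s]]]
    if (is.null(cand)) next
    d <- D[s, ]
    b1 <- r1[cand, 1] * d[1] + r1[cand, 2] * d[2] + r1[cand, 3] * d[3]
    b2 <- r2[cand, 1] * d[1] + r2[cand, 2] * d[2] + r2[cand, 3] * d[3]
    b3 <- r3[cand, 1] * d[1] + r3[cand, 2] * d[2] + r3[cand, 3] * d[3]
    ssum <- b1 + b2 + b3
    ok <- b1 >= tol & b2 >= tol & b3 >= tol & ssum > 1e-12
    if (any(ok)) best_t[s] <- max(1 / ssum[ok])
  }
  if (any(!is.finite(best_t)))
    stop("ray-cast remeshing failed: some directions miss the surface", call. = FALSE)
  verts <- sweep(D * best_t, 2, center, "+")
  surface_mesh(verts, ico$triangles)
}

# ---- the onion mesher -------------------------------------------------------

#' Fill a closed surface with a conforming tetrahedral mesh
#'
#' The enclosed region must be star-shaped with respect to its volume
#' centroid (always true for the convex/ellipsoid-like organs this package
#' targets). The input triangulation becomes the mesh boundary exactly, so
#' the summed element volume equals the enclosed surface volume to round-off.
#' Input surfaces finer than `decimate_triangles` are first remeshed onto an
#' icosphere topology by centroid ray-casting (remeshed vertices lie exactly
#' on the input surface); surfaces too coarse for the requested element
#' volume are midpoint-subdivided (geometry unchanged).
#'
#' @param surface a closed, outward-wound [surface_mesh()], optionally
#'   carrying feature points from [insert_feature_nodes()].
#' @param target_mean_volume_mm3 requested mean tetrahedron volume; typically
#'   set slightly below the image voxel volume.
#' @param decimate_triangles remesh input surfaces with more triangles than
#'   this (default 6000, targeting about 5000 boundary triangles).
#' @return A [tet_mesh()]; if feature points were attached, their node ids
#'   are in `attr(, "feature_node_ids")`.
#' @export
tetrahedralize <- function(surface, target_mean_volume_mm3,
                           decimate_triangles = 6000) {
  stopifnot(inherits(surface, "bmdir_surface"), target_mean_volume_mm3 > 0)
  sc <- .surface_centroid(surface)
  if (sc$volume <= 0)
    stop("surface encloses no volume (check winding)", call. = FALSE)
  ctr <- sc$centroid; V <- sc$volume
  if (!.star_shaped(surface, ctr))
    stop("enclosed region is not star-shaped about its centroid; this mesher requires star-shaped organs",
         call. = FALSE)
  surf <- surface
  if (nrow(surf$triangles) > decimate_triangles) {
    subdiv <- max(0, min(5, round(log(decimate_triangles / 20 / 1.25) / log(4))))
    surf <- .raycast_remesh(surface, ctr, subdiv)
  }
  # refine surface until <= 8 layers suffice for the element budget
  max_layers <- 8
  while (nrow(surf$triangles) * (8 * (max_layers - 1) + 1) <
         V / target_mean_volume_mm3 && nrow(surf$triangles) < 2e5)
    surf <- .subdivide_surface(surf)
  nt <- nrow(surf$triangles)
  n_layers <- max(2, ceiling((V / (target_mean_volume_mm3 * nt) - 1) / 8) + 1)
  tfrac <- (seq_len(n_layers) / n_layers)^0.75

  sv <- surf$vertices; tri <- surf$triangles
  nv <- nrow(sv)
  # nodes: 1 = apex; layers k=1..n_layers hold nv nodes each
  layer_nodes <- lapply(tfrac, function(t) sweep(sweep(sv, 2, ctr) * t, 2, ctr, "+"))
  nodes <- rbind(ctr, do.call(rbind, layer_nodes))
  lid <- function(k, vids) 1L + (k - 1L) * nv + as.integer(vids)

  tets <- vector("list", n_layers)
  # cavity fan: apex to layer-1 triangles
  tets[[1]] <- cbind(1L, lid(1, tri[, 1]), lid(1, tri[, 2]), lid(1, tri[, 3]))
  # prism frusta between consecutive layers, split through their centroids
  cent_nodes <- vector("list", n_layers - 1)
  next_node <- nrow(nodes)
  for (k in seq_len(n_layers - 1)) {
    A1 <- lid(k, tri[, 1]); B1 <- lid(k, tri[, 2]); C1 <- lid(k, tri[, 3])
    A2 <- lid(k + 1, tri[, 1]); B2 <- lid(k + 1, tri[, 2]); C2 <- lid(k + 1, tri[, 3])
    ctrs <- (layer_nodes[[k]][tri[, 1], ] + layer_nodes[[k]][tri[, 2], ] +
             layer_nodes[[k]][tri[, 3], ] +
             layer_nodes[[k + 1]][tri[, 1], ] + layer_nodes[[k + 1]][tri[, 2], ] +
             layer_nodes[[k + 1]][tri[, 3], ]) / 6
    cn <- next_node + seq_len(nt)
    next_node <- next_node + nt
    cent_nodes[[k]] <- ctrs
    quad_tets <- function(P, Q, Qn, Pn) {
      # planar quad ring P-Q-Qn-Pn; diagonal from its min-id corner
      use_PQn <- pmin(P, Qn) < pmin(Q, Pn)
      rbind(cbind(cn, P, Q, ifelse(use_PQn, Qn, Pn)),
            cbind(cn, ifelse(use_PQn, P, Q), Qn, Pn))
    }
    tets[[k + 1]] <- rbind(
      cbind(cn, A1, B1, C1),                  # bottom face
      cbind(cn, A2, B2, C2),                  # top face
      quad_tets(A1, B1, B2, A2),
      quad_tets(B1, C1, C2, B2),
      quad_tets(C1, A1, A2, C2))
  }
  nodes <- rbind(nodes, do.call(rbind, cent_nodes))
  tets <- do.call(rbind, tets)
  tets <- .fix_orientation(tets, nodes)
  surface_ids <- lid(n_layers, seq_len(nv))
  mesh <- tet_mesh(nodes, tets, surface_ids)
  v <- tet_volumes(mesh)
  if (any(v <= 0))
    stop("meshing failure: non-positive tetrahedron produced", call. = FALSE)
  fp <- attr(surface, "feature_points")
  if (!is.null(fp)) mesh <- .insert_nodes(mesh, fp)
  mesh
}

#' Request feature points as mesh nodes
#'
#' Marks physical points (inside the enclosed region or on the surface) that
#' must appear verbatim in the node list after [tetrahedralize()]; their node
#' ids are then reported in `attr(mesh, "feature_node_ids")`. Points that
#' coincide with existing nodes are reused, not duplicated.
#'
#' @param surface a [surface_mesh()].
#' @param points n-by-3 matrix of mm coordinates.
#' @return The surface with the constraint points attached.
#' @export
insert_feature_nodes <- function(surface, points) {
  stopifnot(inherits(surface, "bmdir_surface"))
  points <- rbind(points)
  stopifnot(ncol(points) == 3L)
  attr(surface, "feature_points") <- rbind(attr(surface, "feature_points"), points)
  surface
}

# barycentric coordinates of points wrt every tet is too big; brute-force per
# point (fine for feature-point counts)
.locate_point <- function(mesh, p) {
  n <- mesh$nodes; t <- mesh$tets
  a <- n[t[, 1], , drop = FALSE]
  v1 <- n[t[, 2], , drop = FALSE] - a
  v2 <- n[t[, 3], , drop = FALSE] - a
  v3 <- n[t[, 4], , drop = FALSE] - a
  det <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
         v2[, 1] * (v1[, 2] * v3[, 3] - v1[, 3] * v3[, 2]) +
         v3[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2])
  r <- cbind(p[1] - a[, 1], p[2] - a[, 2], p[3] - a[, 3])
  b1 <- (r[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
         v2[, 1] * (r[, 2] * v3[, 3] - r[, 3] * v3[, 2]) +
         v3[, 1] * (r[, 2] * v2[, 3] - r[, 3] * v2[, 2])) / det
  b2 <- (v1[, 1] * (r[, 2] * v3[, 3] - r[, 3] * v3[, 2]) -
         r[, 1] * (v1[, 2] * v3[, 3] - v1[, 3] * v3[, 2]) +
         v3[, 1] * (v1[, 2] * r[, 3] - v1[, 3] * r[, 2])) / det
  b3 <- (v1[, 1] * (v2[, 2] * r[, 3] - v2[, 3] * r[, 2]) -
         v2[, 1] * (v1[, 2] * r[, 3] - v1[, 3] * r[, 2]) +
         r[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2])) / det
  b0 <- 1 - b1 - b2 - b3
  minb <- pmin(b0, b1, b2, b3)
  best <- which.max(minb)
  list(tet = best, bary = c(b0[best], b1[best], b2[best], b3[best]),
       min_bary = minb[best])
}

.insert_nodes <- function(mesh, points, tol_merge = 1e-6) {
  ids <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    d2 <- (mesh$nodes[, 1] - p[1])^2 + (mesh$nodes[, 2] - p[2])^2 +
          (mesh$nodes[, 3] - p[3])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= tol_merge) { ids[i] <- j; next }
    loc <- .locate_point(mesh, p)
    if (loc$min_bary < -1e-9)
      stop("feature point ", i, " lies outside the meshed region", call. = FALSE)
    new_id <- nrow(mesh$nodes) + 1L
    nodes <- rbind(mesh$nodes, p)
    tt <- mesh$tets[loc$tet, ]
    on_face <- loc$bary < 1e-9
    if (!any(on_face)) {
      reps <- rbind(c(new_id, tt[2], tt[3], tt[4]),
                    c(tt[1], new_id, tt[3], tt[4]),
                    c(tt[1], tt[2], new_id, tt[4]),
                    c(tt[1], tt[2], tt[3], new_id))
      tets <- rbind(mesh$tets[-loc$tet, , drop = FALSE], reps)
    } else if (sum(on_face) == 1L) {
      # on a shared face: split both incident tets 1 -> 3
      face <- tt[!on_face]
      has_face <- rowSums(matrix(mesh$tets %in% face, nrow(mesh$tets), 4)) == 3
      todo <- which(has_face)
      reps <- NULL
      for (ti in todo) {
        tv <- mesh$tets[ti, ]
        for (drop_v in tv[tv %in% face])
          reps <- rbind(reps, replace(tv, match(drop_v, tv), new_id))
      }
      tets <- rbind(mesh$tets[-todo, , drop = FALSE], reps)
    } else {
      stop("feature point ", i, " lies on a mesh edge; perturb it slightly", call. = FALSE)
    }
    tets <- .fix_orientation(tets, nodes)
    mesh$nodes <- nodes
    mesh$tets <- tets
    ids[i] <- new_id
  }
  attr(mesh, "feature_node_ids") <- ids
  mesh
}

# ---- quality ----------------------------------------------------------------

#' Per-tetrahedron quality measures
#'
#' Computes, for every element: signed volume; radius ratio
#' (`3 * inradius / circumradius`); edge-length ratio (min/max edge); minimum
#' and maximum dihedral angle in degrees; the volume-edge-length measure
#' (`6 * sqrt(2) * V / l_rms^3`); and aspect ratio
#' (`l_max / (2 * sqrt(6) * inradius)`). All equal 1 (dihedrals 70.5288 deg)
#' for the regular tetrahedron and degrade toward 0 (or grow without bound,
#' for aspect ratio and dihedral extremes) with element distortion.
#'
#' @param mesh a [tet_mesh()].
#' @return A tibble with one row per tetrahedron.
#' @export
quality_metrics <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tets
  p1 <- n[t[, 1], , drop = FALSE]; p2 <- n[t[, 2], , drop = FALSE]
  p3 <- n[t[, 3], , drop = FALSE]; p4 <- n[t[, 4], , drop = FALSE]
  vol <- tet_volumes(mesh)
  edges <- list(p2 - p1, p3 - p1, p4 - p1, p3 - p2, p4 - p2, p4 - p3)
  el2 <- sapply(edges, function(e) rowSums(e^2))
  el2 <- matrix(el2, ncol = 6)
  el <- sqrt(el2)
  lmin <- apply(el, 1, min); lmax <- apply(el, 1, max)
  lrms <- sqrt(rowMeans(el2))
  tri_area <- function(a, b, c) {
    u <- b - a; w <- c - a
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
  A <- tri_area(p2, p3, p4) + tri_area(p1, p3, p4) +
       tri_area(p1, p2, p4) + tri_area(p1, p2, p3)
  r_in <- 3 * vol / A
  # circumcenter offset: (|a|^2 (b x c) + |b|^2 (c x a) + |c|^2 (a x b)) / (2 det)
  a <- p2 - p1; b <- p3 - p1; cc <- p4 - p1
  cross <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                u[, 1] * w[, 2] - u[, 2] * w[, 1])
  det6 <- 6 * vol
  num <- rowSums(a^2) * cross(b, cc) + rowSums(b^2) * cross(cc, a) +
         rowSums(cc^2) * cross(a, b)
  R_circ <- sqrt(rowSums((num / (2 * det6))^2))
  # dihedral angles from outward face normals: theta = pi - angle(n_i, n_j)
  nrm <- list(cross(p3 - p2, p4 - p2),    # face opposite p1
              cross(p4 - p1, p3 - p1),    # opposite p2 (outward for +vol)
              cross(p2 - p1, p4 - p1),    # opposite p3
              cross(p3 - p1, p2 - p1))    # opposite p4
  nrm <- lapply(nrm, function(x) x / pmax(sqrt(rowSums(x^2)), 1e-300))
  edge_faces <- rbind(c(3, 4), c(2, 4), c(2, 3), c(1, 4), c(1, 3), c(1, 2))
  dih <- sapply(seq_len(6), function(e) {
    cosang <- rowSums(nrm[[edge_faces[e, 1]]] * nrm[[edge_faces[e, 2]]])
    180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  })
  dih <- matrix(dih, ncol = 6)
  tibble::tibble(
    tet = seq_len(nrow(t)),
    volume = vol,
    radius_ratio = ifelse(vol > 0 & is.finite(R_circ) & R_circ > 0,
                          3 * r_in / R_circ, 0),
    edge_ratio = lmin / lmax,
    min_dihedral_deg = apply(dih, 1, min),
    max_dihedral_deg = apply(dih, 1, max),
    volume_edge = 6 * sqrt(2) * vol / lrms^3,
    aspect_ratio = ifelse(r_in > 0, lmax / (2 * sqrt(6) * r_in), Inf))
}

#' Min/mean/max summary of mesh quality
#' @param mesh a [tet_mesh()] (or a quality tibble from [quality_metrics()]).
#' @return A tibble with one row per quality measure.
#' @export
quality_summary <- function(mesh) {
  q <- if (inherits(mesh, "bmdir_tetmesh")) quality_metrics(mesh) else mesh
  meas <- setdiff(names(q), "tet")
  tibble::tibble(
    measure = meas,
    min = vapply(meas, function(m) min(q[[m]]), numeric(1)),
    mean = vapply(meas, function(m) mean(q[[m]]), numeric(1)),
    max = vapply(meas, function(m) max(q[[m]]), numeric(1)))
}

# ---- exports ----------------------------------------------------------------

#' Write a tetrahedral mesh as legacy ASCII VTK unstructured grid
#' @param mesh a [tet_mesh()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tetmesh_vtk <- function(mesh, path) {
  n <- mesh$nodes; t <- mesh$tets
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "bmdir tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(n))), con)
  writeLines(sprintf("%.9g %.9g %.9g", n[, 1], n[, 2], n[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(t), 5 * nrow(t)), con)
  writeLines(sprintf("4 %d %d %d %d", t[, 1] - 1L, t[, 2] - 1L,
                     t[, 3] - 1L, t[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(t)), con)
  writeLines(rep("10", nrow(t)), con)
  invisible(path)
}

#' Write a mesh (with optional boundary conditions) as an Abaqus INP deck
#'
#' Nodes, C3D4 elements, and the surface node set, for cross-checking against
#' external FEM solvers.
#'
#' @param mesh a [tet_mesh()].
#' @param path destination path.
#' @param dirichlet optional named list/matrix of prescribed displacements
#'   (rows = node ids in `mesh$surface_node_ids` order) written as BOUNDARY
#'   cards.
#' @return `path`, invisibly.
#' @export
write_abaqus_inp <- function(mesh, path, dirichlet = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("bmdir organ mesh", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("*NSET, NSET=SURFACE", con)
  ids <- mesh$surface_node_ids
  for (s in seq(1, length(ids), by = 8))
    writeLines(paste(ids[s:min(length(ids), s + 7)], collapse = ", "), con)
  if (!is.null(dirichlet)) {
    writeLines("*BOUNDARY", con)
    for (r in seq_len(nrow(dirichlet)))
      for (dof in 1:3)
        writeLines(sprintf("%d, %d, %d, %.9g", ids[r], dof, dof,
                           dirichlet[r, dof]), con)
  }
  invisible(path)
}
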
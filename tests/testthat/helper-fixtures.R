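# Shared fixture builders (all generated in code) and independent brute-force
# oracles used across the suite.

make_sphere_mask <- function(radius_mm = 10, dim = c(32, 32, 32),
                             spacing = c(1, 1, 1), center = NULL) {
  if (is.null(center)) center <- (dim - 1) / 2 * spacing
  v <- array(0, dim)
  idx <- seq_len(prod(dim))
  i <- (idx - 1) %% dim[1]
  j <- ((idx - 1) %/% dim[1]) %% dim[2]
  k <- (idx - 1) %/% (dim[1] * dim[2])
  r <- sqrt((i * spacing[1] - center[1])^2 + (j * spacing[2] - center[2])^2 +
            (k * spacing[3] - center[3])^2)
  v[r <= radius_mm] <- 1
  binary_mask(v, spacing)
}

make_ellipsoid_mask <- function(semiaxes, dim, spacing = c(1, 1, 1),
                                center = NULL) {
  if (is.null(center)) center <- (dim - 1) / 2 * spacing
  v <- array(0, dim)
  idx <- seq_len(prod(dim))
  i <- (idx - 1) %% dim[1]
  j <- ((idx - 1) %/% dim[1]) %% dim[2]
  k <- (idx - 1) %/% (dim[1] * dim[2])
  lev <- ((i * spacing[1] - center[1]) / semiaxes[1])^2 +
         ((j * spacing[2] - center[2]) / semiaxes[2])^2 +
         ((k * spacing[3] - center[3]) / semiaxes[3])^2
  v[lev <= 1] <- 1
  binary_mask(v, spacing)
}

# an affine displacement field u(x) = A x + b evaluated on a grid
make_affine_dvf <- function(A, b, dim = c(16, 16, 16), spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  ref <- image_volume(array(0, dim), spacing, origin)
  pts <- voxel_centers(ref)
  u <- t(A %*% t(pts)) + rep(b, each = nrow(pts))
  displacement_field(array(c(u[, 1], u[, 2], u[, 3]), c(dim, 3)), spacing, origin)
}

affine_eval <- function(A, b, pts) t(A %*% t(pts)) + rep(b, each = nrow(pts))

# compact phantom for unit tests (fast; the acceptance suite uses defaults)
small_phantom_spec <- function(...) {
  phantom_spec(dim = c(40, 40, 40), spacing = c(1, 1, 1),
               organ_semiaxes = c(12, 10.5, 13),
               tube_radius = 2.5,
               tube_control = rbind(c(19.5, 19.5, 10.5), c(19.5, 19.5, 28.5)),
               push_sigma = 8, a_max = 5, ...)
}

# smooth random blob mask on a small grid (nonempty, interior not touching
# the border), for metric-oracle comparisons
random_blob_mask <- function(dim = c(20, 20, 20), spacing = c(1, 1, 1)) {
  repeat {
    f <- array(rnorm(prod(dim)), dim)
    # crude smoothing by repeated 6-neighbour averaging
    for (it in 1:6) {
      f <- (f +
        f[c(1, 1:(dim[1] - 1)), , ] + f[c(2:dim[1], dim[1]), , ] +
        f[, c(1, 1:(dim[2] - 1)), ] + f[, c(2:dim[2], dim[2]), ] +
        f[, , c(1, 1:(dim[3] - 1))] + f[, , c(2:dim[3], dim[3])]) / 7
    }
    thr <- stats::quantile(f, 0.85)
    v <- array(as.numeric(f > thr), dim)
    v[c(1, dim[1]), , ] <- 0; v[, c(1, dim[2]), ] <- 0; v[, , c(1, dim[3])] <- 0
    if (sum(v) >= 10) return(binary_mask(v, spacing))
  }
}

# ---- independent brute-force oracles ---------------------------------------

mask_voxel_coords <- function(mask, which_voxels) {
  d <- dim(mask$voxels)
  b <- which_voxels
  i <- (b - 1) %% d[1]
  j <- ((b - 1) %/% d[1]) %% d[2]
  k <- (b - 1) %/% (d[1] * d[2])
  cbind(mask$origin[1] + i * mask$spacing[1],
        mask$origin[2] + j * mask$spacing[2],
        mask$origin[3] + k * mask$spacing[3])
}

dice_bruteforce <- function(a, b) {
  av <- a$voxels > 0.5; bv <- b$voxels > 0.5
  inter <- 0
  for (lin in which(av)) if (bv[lin]) inter <- inter + 1
  2 * inter / (sum(av) + sum(bv))
}

surface_distances_bruteforce <- function(a, b) {
  pa <- mask_voxel_coords(a, which(mask_boundary(a)))
  pb <- mask_voxel_coords(b, which(mask_boundary(b)))
  dmin_ab <- numeric(nrow(pa))
  for (r in seq_len(nrow(pa)))
    dmin_ab[r] <- sqrt(min((pb[, 1] - pa[r, 1])^2 + (pb[, 2] - pa[r, 2])^2 +
                           (pb[, 3] - pa[r, 3])^2))
  dmin_ba <- numeric(nrow(pb))
  for (r in seq_len(nrow(pb)))
    dmin_ba[r] <- sqrt(min((pa[, 1] - pb[r, 1])^2 + (pa[, 2] - pb[r, 2])^2 +
                           (pa[, 3] - pb[r, 3])^2))
  list(hausdorff_mm = max(max(dmin_ab), max(dmin_ba)),
       mean_surface_distance_mm = (mean(dmin_ab) + mean(dmin_ba)) / 2)
}

trd_fraction_bruteforce <- function(dvf_a, dvf_b, mask, threshold) {
  above <- 0; total <- 0
  sel <- which(mask$voxels > 0.5)
  npl <- prod(dim(mask$voxels))
  for (lin in sel) {
    dx <- dvf_a$vectors[lin] - dvf_b$vectors[lin]
    dy <- dvf_a$vectors[lin + npl] - dvf_b$vectors[lin + npl]
    dz <- dvf_a$vectors[lin + 2 * npl] - dvf_b$vectors[lin + 2 * npl]
    total <- total + 1
    if (sqrt(dx^2 + dy^2 + dz^2) > threshold) above <- above + 1
  }
  above / total
}

# trilinear interpolation written independently (scalar, one point)
trilinear_bruteforce <- function(vol, p, fill = 0) {
  d <- dim(vol$voxels)
  t <- (p - vol$origin) / vol$spacing
  if (any(t < 0) || any(t > d - 1)) return(fill)
  i0 <- pmin(floor(t), d - 2)
  f <- t - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * vol$voxels[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

random_rotation <- function() {
  # QR of a Gaussian matrix, det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# exact distance from points to a triangle mesh (point-to-triangle, looped;
# test oracle only)
point_to_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

point_to_surface_distance <- function(pts, surface) {
  v <- surface$vertices; tr <- surface$triangles
  vapply(seq_len(nrow(pts)), function(q) {
    p <- pts[q, ]
    # prefilter by vertex distance to keep the oracle affordable
    d2v <- (v[, 1] - p[1])^2 + (v[, 2] - p[2])^2 + (v[, 3] - p[3])^2
    near <- which(rowSums(matrix(d2v[tr] <= (sqrt(min(d2v)) + 2)^2,
                                 nrow(tr), 3)) > 0)
    min(vapply(near, function(f)
      point_to_triangle(p, v[tr[f, 1], ], v[tr[f, 2], ], v[tr[f, 3], ]),
      numeric(1)))
  }, numeric(1))
}
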
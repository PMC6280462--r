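# Trilinear interpolation on axis-aligned grids. All heavy paths are fully
# vectorised over the query points.

# points: n x 3 physical mm. Returns list(i0 = n x 3 integer 0-based lower
# corner, f = n x 3 fractional offset, inside = logical n).
.tri_locate <- function(dim, spacing, origin, points, clamp = TRUE) {
  t1 <- (points[, 1] - origin[1]) / spacing[1]
  t2 <- (points[, 2] - origin[2]) / spacing[2]
  t3 <- (points[, 3] - origin[3]) / spacing[3]
  inside <- t1 >= 0 & t1 <= dim[1] - 1 &
            t2 >= 0 & t2 <= dim[2] - 1 &
            t3 >= 0 & t3 <= dim[3] - 1
  if (clamp) {
    t1 <- pmin(pmax(t1, 0), dim[1] - 1)
    t2 <- pmin(pmax(t2, 0), dim[2] - 1)
    t3 <- pmin(pmax(t3, 0), dim[3] - 1)
  }
  i1 <- pmin(floor(t1), dim[1] - 2); i2 <- pmin(floor(t2), dim[2] - 2)
  i3 <- pmin(floor(t3), dim[3] - 2)
  list(i0 = cbind(i1, i2, i3),
       f  = cbind(t1 - i1, t2 - i2, t3 - i3),
       inside = inside)
}

# voxels: 3-D array; loc from .tri_locate. Vectorised 8-corner gather.
.tri_gather <- function(voxels, loc) {
  d <- dim(voxels)
  i <- loc$i0; f <- loc$f
  base <- 1 + i[, 1] + d[1] * (i[, 2] + d[2] * i[, 3])
  oy <- d[1]; oz <- d[1] * d[2]
  f1 <- f[, 1]; f2 <- f[, 2]; f3 <- f[, 3]
  g1 <- 1 - f1; g2 <- 1 - f2; g3 <- 1 - f3
  voxels[base]                * (g1 * g2 * g3) +
  voxels[base + 1]            * (f1 * g2 * g3) +
  voxels[base + oy]           * (g1 * f2 * g3) +
  voxels[base + oy + 1]       * (f1 * f2 * g3) +
  voxels[base + oz]           * (g1 * g2 * f3) +
  voxels[base + oz + 1]       * (f1 * g2 * f3) +
  voxels[base + oz + oy]      * (g1 * f2 * f3) +
  voxels[base + oz + oy + 1]  * (f1 * f2 * f3)
}

sample_scalar <- function(vol, points, fill = NA_real_, clamp = FALSE) {
  points <- rbind(points)
  loc <- .tri_locate(vol_dim(vol), vol$spacing, vol$origin, points, clamp = TRUE)
  v <- .tri_gather(vol$voxels, loc)
  if (!clamp) v[!loc$inside] <- fill
  v
}

#' Sample a displacement field at physical points
#'
#' Each vector component is interpolated trilinearly at the query points.
#' Points outside the grid are clamped to the grid edge (surface nodes may sit
#' exactly on, or round just beyond, the boundary).
#'
#' @param dvf a [displacement_field()].
#' @param points n-by-3 matrix of mm coordinates.
#' @return n-by-3 matrix of displacement vectors in mm.
#' @export
sample_dvf <- function(dvf, points) {
  stopifnot(inherits(dvf, "bmdir_dvf"))
  if (!all(is.finite(dvf$vectors))) stop("NaN in displacement field", call. = FALSE)
  points <- rbind(points)
  loc <- .tri_locate(vol_dim(dvf), dvf$spacing, dvf$origin, points, clamp = TRUE)
  out <- matrix(0, nrow(points), 3)
  for (c in 1:3) out[, c] <- .tri_gather(dvf$vectors[, , , c], loc)
  out
}

#' Resample a volume to a new voxel spacing
#'
#' The physical extent is preserved within one voxel: the new grid starts at
#' the same origin and covers the old voxel-center extent with trilinear
#' interpolation at the new voxel centers. Masks are resampled trilinearly and
#' re-thresholded at 0.5.
#'
#' @param vol an [image_volume()] or [binary_mask()].
#' @param new_spacing target spacing `(sx, sy, sz)` in mm.
#' @return A volume of the same class on the new grid.
#' @export
resample <- function(vol, new_spacing) {
  stopifnot(inherits(vol, "bmdir_image"))
  new_spacing <- rep_len(as.numeric(new_spacing), 3L)
  if (any(new_spacing <= 0)) stop("new_spacing must be positive", call. = FALSE)
  d <- vol_dim(vol)
  extent <- (d - 1) * vol$spacing           # voxel-center extent
  nd <- pmax(2L, as.integer(floor(extent / new_spacing + 1e-9)) + 1L)
  if (any(extent < new_spacing))
    stop("degenerate output grid: fewer than 2 voxels on some axis", call. = FALSE)
  out <- image_volume(array(0, nd), new_spacing, vol$origin)
  pts <- voxel_centers(out)
  vals <- sample_scalar(vol, pts, clamp = TRUE)
  if (inherits(vol, "bmdir_mask")) {
    binary_mask(array(as.numeric(vals >= 0.5), nd), new_spacing, vol$origin)
  } else {
    image_volume(array(vals, nd), new_spacing, vol$origin)
  }
}

#' Warp a moving image onto the reference grid with a displacement field
#'
#' The output lives on the grid of `dvf` (the reference grid). The value at a
#' fixed voxel center `x` is the trilinear sample of `moving` at `x + u(x)`
#' (pull-back warping). Samples falling outside the moving image take `fill`.
#'
#' @param moving the image to be warped (any grid).
#' @param dvf the [displacement_field()] on the reference grid.
#' @param fill value for out-of-bounds samples.
#' @return An [image_volume()] on the reference grid.
#' @export
warp_image <- function(moving, dvf, fill = 0) {
  stopifnot(inherits(moving, "bmdir_image"), inherits(dvf, "bmdir_dvf"))
  pts <- voxel_centers(dvf)
  d <- vol_dim(dvf)
  u <- cbind(as.numeric(dvf$vectors[, , , 1]),
             as.numeric(dvf$vectors[, , , 2]),
             as.numeric(dvf$vectors[, , , 3]))
  vals <- sample_scalar(moving, pts + u, fill = fill, clamp = FALSE)
  image_volume(array(vals, d), dvf$spacing, dvf$origin)
}

#' Warp a binary structure mask with a displacement field
#'
#' Trilinear warp of the 0/1 field followed by a 0.5 threshold.
#'
#' @param structure a [binary_mask()] on the moving grid.
#' @inheritParams warp_image
#' @return A [binary_mask()] on the reference grid.
#' @export
warp_mask <- function(structure, dvf) {
  stopifnot(inherits(structure, "bmdir_mask"))
  w <- warp_image(structure, dvf, fill = 0)
  binary_mask(array(as.numeric(w$voxels >= 0.5), vol_dim(w)), w$spacing, w$origin)
}
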
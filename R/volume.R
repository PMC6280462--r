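#' @importFrom stats rnorm sd quantile median setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# ---- grid helpers -----------------------------------------------------------

grid_meta <- function(dim, spacing, origin) {
  dim <- as.integer(dim); spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(dim) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be positive and finite", call. = FALSE)
  if (any(dim < 2L))
    stop("grid must have at least 2 voxels per axis", call. = FALSE)
  list(dim = dim, spacing = spacing, origin = origin)
}

#' Construct a 3-D scalar image volume
#'
#' An `bmdir_image` is a dense 3-D scalar array on an axis-aligned grid with
#' voxel-center physical coordinates: voxel index `(i, j, k)` (0-based) sits at
#' `origin + c(i, j, k) * spacing`, in millimetres. The first array index is
#' the fastest-varying (x) axis.
#'
#' @param voxels numeric 3-D array of intensities.
#' @param spacing voxel spacing `(sx, sy, sz)` in mm; all positive.
#' @param origin physical coordinate of voxel `(0, 0, 0)` in mm.
#' @return An object of class `bmdir_image`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  g <- grid_meta(dim(voxels), spacing, origin)
  structure(list(voxels = voxels, spacing = g$spacing, origin = g$origin),
            class = "bmdir_image")
}

#' Construct a binary mask on an image grid
#'
#' Same grid model as [image_volume()]; voxel values must be 0 or 1.
#'
#' @inheritParams image_volume
#' @return An object of class `c("bmdir_mask", "bmdir_image")`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  v <- as.numeric(voxels)
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop("mask voxels must all be 0 or 1", call. = FALSE)
  img <- image_volume(array(v, dim(voxels)), spacing, origin)
  class(img) <- c("bmdir_mask", "bmdir_image")
  img
}

#' Construct a displacement vector field
#'
#' One 3-vector per voxel of the reference grid, in mm, using the pull-back
#' convention: the field value `u(x)` at fixed-space point `x` points to the
#' corresponding moving-space point `x + u(x)`.
#'
#' @param vectors numeric 4-D array `(nx, ny, nz, 3)` of displacements in mm.
#' @inheritParams image_volume
#' @return An object of class `bmdir_dvf`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(vectors), length(dim(vectors)) == 4L, dim(vectors)[4] == 3L)
  if (!all(is.finite(vectors)))
    stop("displacement field must be finite everywhere", call. = FALSE)
  g <- grid_meta(dim(vectors)[1:3], spacing, origin)
  structure(list(vectors = vectors, spacing = g$spacing, origin = g$origin),
            class = "bmdir_dvf")
}

#' A zero displacement field on the grid of a reference image
#' @param ref an [image_volume()] (or mask) providing the grid.
#' @return A [displacement_field()] of zeros.
#' @export
zero_dvf <- function(ref) {
  d <- vol_dim(ref)
  displacement_field(array(0, c(d, 3L)), ref$spacing, ref$origin)
}

vol_dim <- function(x) {
  if (inherits(x, "bmdir_dvf")) dim(x$vectors)[1:3] else dim(x$voxels)
}

#' @export
print.bmdir_image <- function(x, ...) {
  d <- vol_dim(x)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
print.bmdir_dvf <- function(x, ...) {
  d <- vol_dim(x)
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<bmdir_dvf> %d x %d x %d voxels, |u| in [%.3g, %.3g] mm\n",
              d[1], d[2], d[3], min(mag), max(mag)))
  invisible(x)
}

#' Check that two objects share a grid
#'
#' Grids are compatible when shapes match and spacing/origin agree within
#' `tol` mm.
#' @param a,b image volumes, masks or displacement fields.
#' @param tol agreement tolerance in mm.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(vol_dim(a), vol_dim(b)))
    stop("grids differ in shape", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > tol || max(abs(a$origin - b$origin)) > tol)
    stop("grids differ in spacing or origin", call. = FALSE)
  invisible(TRUE)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(vol_dim(a), vol_dim(b)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

#' Physical coordinates of all voxel centers
#' @param vol a grid-carrying object.
#' @return n-by-3 matrix of mm coordinates, x fastest.
#' @export
voxel_centers <- function(vol) {
  d <- vol_dim(vol)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Construct a set of paired registration landmarks
#'
#' Pairs of corresponding physical points: `fixed` in the reference image,
#' `moving` in the moving image, both in mm.
#'
#' @param fixed,moving n-by-3 numeric matrices of mm coordinates.
#' @param labels optional character labels, one per pair.
#' @return A tibble of class `bmdir_landmarks` with columns
#'   `label, fx, fy, fz, mx, my, mz`.
#' @export
landmark_set <- function(fixed, moving, labels = NULL) {
  fixed <- rbind(fixed); moving <- rbind(moving)
  stopifnot(ncol(fixed) == 3L, ncol(moving) == 3L, nrow(fixed) == nrow(moving),
            nrow(fixed) >= 1L)
  if (is.null(labels)) labels <- sprintf("L%02d", seq_len(nrow(fixed)))
  out <- tibble::tibble(label = as.character(labels),
                        fx = fixed[, 1], fy = fixed[, 2], fz = fixed[, 3],
                        mx = moving[, 1], my = moving[, 2], mz = moving[, 3])
  class(out) <- c("bmdir_landmarks", class(out))
  out
}

landmark_fixed <- function(lm) as.matrix(lm[, c("fx", "fy", "fz")])
landmark_moving <- function(lm) as.matrix(lm[, c("mx", "my", "mz")])

# mask morphology on the voxel lattice (6-connected), used by several modules

shift_array <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

erode6 <- function(m) {
  a <- m
  a <- a & shift_array(m,  1, 0, 0) & shift_array(m, -1, 0, 0)
  a <- a & shift_array(m, 0,  1, 0) & shift_array(m, 0, -1, 0)
  a <- a & shift_array(m, 0, 0,  1) & shift_array(m, 0, 0, -1)
  a
}

#' Boundary voxels of a mask
#'
#' The boundary set is the mask minus its 6-connected erosion.
#' @param mask a [binary_mask()].
#' @return Logical 3-D array marking boundary voxels.
#' @export
mask_boundary <- function(mask) {
  m <- mask$voxels > 0.5
  m & !erode6(m)
}
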
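# Synthetic multistage deformable phantom: an ellipsoidal organ containing a
# tube, deformed through graded stages by a smooth balloon-like radial push
# with an analytic ground-truth displacement field.

#' Run code with a locally fixed RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so generators are deterministic without clobbering the
#' session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Periodic Gaussian smoothing via FFT; sigma_vox per axis (in voxels).
smooth_gaussian <- function(a, sigma_vox) {
  d <- dim(a)
  sigma_vox <- rep_len(sigma_vox, 3L)
  g <- lapply(1:3, function(ax) {
    x <- seq_len(d[ax]) - 1
    x <- pmin(x, d[ax] - x)                 # circular distance to index 0
    k <- exp(-x^2 / (2 * max(sigma_vox[ax], 1e-8)^2))
    k / sum(k)
  })
  kern <- outer(outer(g[[1]], g[[2]]), g[[3]])
  Re(stats::fft(stats::fft(a) * stats::fft(kern), inverse = TRUE)) / prod(d)
}

#' Specify the synthetic deformable phantom
#'
#' The phantom emulates a prostate-like organ (an ellipsoid, un-deformed full
#' dimensions 44.2 x 38.5 x 50.7 mm) with an internal bright tube, deformed
#' through `n_stages` graded, reproducible stages by a balloon-like radial
#' push from a centre below the organ. Stage amplitudes follow a linear
#' schedule `a_i = (i / n_stages) * a_max`.
#'
#' @param dim grid shape, default `c(64, 64, 64)`.
#' @param spacing voxel spacing in mm, default 1 mm isotropic.
#' @param origin grid origin in mm.
#' @param organ_semiaxes ellipsoid semi-axes in mm.
#' @param organ_center organ centre in mm (default: grid centre).
#' @param tube_radius tube radius in mm.
#' @param tube_control tube centreline control points (n x 3 mm); linearly
#'   interpolated. Default: a straight segment along z through the organ.
#' @param push_center balloon push centre in mm (default: below the organ on
#'   its z axis).
#' @param push_sigma balloon push width sigma in mm.
#' @param a_max maximum push amplitude in mm at the final stage.
#' @param n_stages number of deformation stages (default 10).
#' @param texture_seed RNG seed for the organ texture.
#' @return An object of class `bmdir_phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 64),
                         spacing = c(1, 1, 1),
                         origin = c(0, 0, 0),
                         organ_semiaxes = c(22.1, 19.25, 25.35),
                         organ_center = NULL,
                         tube_radius = 3,
                         tube_control = NULL,
                         push_center = NULL,
                         push_sigma = 12,
                         a_max = 8,
                         n_stages = 10,
                         texture_seed = 20181204) {
  g <- grid_meta(dim, spacing, origin)
  if (is.null(organ_center))
    organ_center <- g$origin + (g$dim - 1) / 2 * g$spacing
  if (is.null(tube_control))
    tube_control <- rbind(organ_center - c(0, 0, 18), organ_center + c(0, 0, 18))
  if (is.null(push_center))
    push_center <- organ_center - c(0, 0, organ_semiaxes[3] + 16)
  spec <- structure(list(dim = g$dim, spacing = g$spacing, origin = g$origin,
                         organ_semiaxes = as.numeric(organ_semiaxes),
                         organ_center = as.numeric(organ_center),
                         tube_radius = tube_radius,
                         tube_control = rbind(tube_control),
                         push_center = as.numeric(push_center),
                         push_sigma = push_sigma, a_max = a_max,
                         n_stages = as.integer(n_stages),
                         texture_seed = texture_seed),
                    class = "bmdir_phantom_spec")
  # organ must fit the grid with a 2-voxel margin
  lo <- spec$organ_center - spec$organ_semiaxes
  hi <- spec$organ_center + spec$organ_semiaxes
  glo <- g$origin + 2 * g$spacing
  ghi <- g$origin + (g$dim - 3) * g$spacing
  if (any(lo < glo) || any(hi > ghi))
    stop("organ does not fit inside the grid with a 2-voxel margin", call. = FALSE)
  spec
}

# --- analytic geometry -------------------------------------------------------

.ellipsoid_level <- function(points, center, semiaxes) {
  ((points[, 1] - center[1]) / semiaxes[1])^2 +
  ((points[, 2] - center[2]) / semiaxes[2])^2 +
  ((points[, 3] - center[3]) / semiaxes[3])^2
}

# distance from points to a polyline (control points linearly interpolated)
.polyline_distance <- function(points, control) {
  n <- nrow(points)
  dmin <- rep(Inf, n)
  for (s in seq_len(nrow(control) - 1)) {
    p0 <- control[s, ]; p1 <- control[s + 1, ]
    v <- p1 - p0; vv <- sum(v^2)
    t <- ((points[, 1] - p0[1]) * v[1] + (points[, 2] - p0[2]) * v[2] +
          (points[, 3] - p0[3]) * v[3]) / vv
    t <- pmin(pmax(t, 0), 1)
    dx <- points[, 1] - (p0[1] + t * v[1])
    dy <- points[, 2] - (p0[2] + t * v[2])
    dz <- points[, 3] - (p0[3] + t * v[3])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2 + dz^2))
  }
  dmin
}

#' Smooth balloon-push displacement field (analytic)
#'
#' The radial bump `u(x) = a (r/sigma) exp((1 - (r/sigma)^2)/2) rhat` with
#' `r = ||x - center||`: analytic everywhere (no singularity at the centre),
#' peak magnitude `a` at `r = sigma`, decaying as a Gaussian beyond. This is
#' the ground-truth deformation model of the synthetic phantom.
#'
#' @param points n-by-3 matrix of mm coordinates.
#' @param center push centre (mm).
#' @param sigma push width (mm).
#' @param a peak amplitude (mm).
#' @return n-by-3 matrix of displacements in mm.
#' @export
push_displacement <- function(points, center, sigma, a) {
  dx <- points[, 1] - center[1]
  dy <- points[, 2] - center[2]
  dz <- points[, 3] - center[3]
  r2 <- dx^2 + dy^2 + dz^2
  s <- (a / sigma) * exp((1 - r2 / sigma^2) / 2)   # = a f(r)/r, finite at r = 0
  cbind(dx * s, dy * s, dz * s)
}

.phantom_masks <- function(spec, points = NULL) {
  pts <- if (is.null(points)) NULL else points
  ref <- image_volume(array(0, spec$dim), spec$spacing, spec$origin)
  if (is.null(pts)) pts <- voxel_centers(ref)
  organ <- .ellipsoid_level(pts, spec$organ_center, spec$organ_semiaxes) <= 1
  tube <- .polyline_distance(pts, spec$tube_control) <= spec$tube_radius
  list(organ = organ, tube = tube & organ)
}

.phantom_texture <- function(spec) {
  msk <- .phantom_masks(spec)
  with_seed(spec$texture_seed, {
    blobs <- smooth_gaussian(array(rnorm(prod(spec$dim)), spec$dim), 2)
  })
  blobs <- blobs / stats::sd(blobs)
  tex <- array(30, spec$dim)
  tex[msk$organ] <- 100 + 35 * blobs[msk$organ]
  tex[msk$tube] <- 220
  tex <- smooth_gaussian(tex, 0.6)   # soften edges so warping interpolates well
  image_volume(tex, spec$spacing, spec$origin)
}

# invert y = x + u(x) by fixed-point iteration psi <- y - u(psi); where the
# plain iteration is not contractive (||grad u|| can exceed 1 close to the
# push centre, outside the organ, even though the map itself stays bijective
# with J > 0) fall back to the damped form psi <- psi - w (psi + u(psi) - y)
.invert_push <- function(points, spec, a, tol = 1e-3, max_iter = 50) {
  psi <- points
  for (it in seq_len(max_iter)) {
    u <- push_displacement(psi, spec$push_center, spec$push_sigma, a)
    new <- points - u
    delta <- max(abs(new - psi))
    psi <- new
    if (delta < tol) return(psi)
  }
  w <- 0.5
  for (it in seq_len(300)) {
    u <- push_displacement(psi, spec$push_center, spec$push_sigma, a)
    step <- psi + u - points
    psi <- psi - w * step
    if (max(abs(step)) * w < tol) return(psi)
  }
  stop("fixed-point inversion of the stage deformation did not converge",
       call. = FALSE)
}

#' Generate the multistage deformable phantom
#'
#' Produces `n_stages + 1` stages (stage 0 is the un-deformed reference). Each
#' stage carries the reference image, the deformed image (built by resampling
#' the reference texture at the inverse map, so the ground-truth field is
#' exactly the pull-back displacement), reference and deformed organ and tube
#' masks, masked-interior image variants, the analytic ground-truth field and
#' a small landmark set along the tube.
#'
#' @param spec a [phantom_spec()].
#' @param stages which stage indices to generate (default all of
#'   `0:n_stages`).
#' @return A list of `bmdir_phantom_stage` objects.
#' @export
generate_phantom <- function(spec, stages = NULL) {
  stopifnot(inherits(spec, "bmdir_phantom_spec"))
  if (is.null(stages)) stages <- 0:spec$n_stages
  ref <- .phantom_texture(spec)
  pts <- voxel_centers(ref)
  msk0 <- .phantom_masks(spec)
  organ0 <- binary_mask(array(as.numeric(msk0$organ), spec$dim), spec$spacing, spec$origin)
  tube0 <- binary_mask(array(as.numeric(msk0$tube), spec$dim), spec$spacing, spec$origin)
  ref_masked <- mask_interior(ref, organ0)
  lm_fixed <- .phantom_landmark_points(spec)

  lapply(stages, function(i) {
    a_i <- (i / spec$n_stages) * spec$a_max
    u <- push_displacement(pts, spec$push_center, spec$push_sigma, a_i)
    dvf <- displacement_field(array(c(u[, 1], u[, 2], u[, 3]), c(spec$dim, 3L)),
                              spec$spacing, spec$origin)
    if (i == 0) {
      img_def <- ref; organ_def <- organ0; tube_def <- tube0
    } else {
      psi <- .invert_push(pts, spec, a_i)
      vals <- sample_scalar(ref, psi, clamp = TRUE)
      img_def <- image_volume(array(vals, spec$dim), spec$spacing, spec$origin)
      mdef <- .phantom_masks(spec, points = psi)
      organ_def <- binary_mask(array(as.numeric(mdef$organ), spec$dim),
                               spec$spacing, spec$origin)
      tube_def <- binary_mask(array(as.numeric(mdef$tube), spec$dim),
                              spec$spacing, spec$origin)
    }
    jac <- jacobian_map(dvf, organ0)
    if (jac$min <= 0)
      stop("stage ", i, ": ground-truth Jacobian is not positive everywhere ",
           "inside the organ; reduce a_max or widen push_sigma", call. = FALSE)
    lm_moving <- lm_fixed +
      push_displacement(lm_fixed, spec$push_center, spec$push_sigma, a_i)
    structure(list(
      stage = i,
      image = ref, image_masked = ref_masked,
      image_def = img_def,
      image_def_masked = mask_interior(img_def, organ_def),
      organ = organ0, tube = tube0,
      organ_def = organ_def, tube_def = tube_def,
      dvf_gt = dvf,
      jacobian_min = jac$min, jacobian_mean = jac$mean,
      landmarks = landmark_set(lm_fixed, lm_moving)
    ), class = "bmdir_phantom_stage")
  })
}

.phantom_landmark_points <- function(spec) {
  # six landmarks along/around the tube, emulating vessel-bifurcation picks
  ctr <- spec$organ_center
  r <- spec$tube_radius
  rbind(ctr + c( r + 2,  0, -12),
        ctr + c(-r - 2,  0,  -6),
        ctr + c( 0,  r + 2,   0),
        ctr + c( 0, -r - 2,   6),
        ctr + c( r + 2,  0,  12),
        ctr + c(-2, -2, 0))
}

#' @export
print.bmdir_phantom_stage <- function(x, ...) {
  cat(sprintf("<bmdir_phantom_stage> stage %d, mean organ Jacobian %.4f (min %.4f)\n",
              x$stage, x$jacobian_mean, x$jacobian_min))
  invisible(x)
}

#' Override the organ interior with its mean intensity
#'
#' Emulates a feature-poor modality: voxels strictly inside the organ (after a
#' 1-voxel erosion, so the boundary shell and its contrast survive) are set to
#' the mean intensity over the whole organ; everything else is untouched.
#'
#' @param img an [image_volume()].
#' @param organ a [binary_mask()] on the same grid.
#' @return An [image_volume()].
#' @export
mask_interior <- function(img, organ) {
  stopifnot(inherits(img, "bmdir_image"), inherits(organ, "bmdir_mask"))
  check_same_grid(img, organ)
  m <- organ$voxels > 0.5
  if (!any(m)) stop("organ mask is empty", call. = FALSE)
  interior <- erode6(m)
  out <- img$voxels
  out[interior] <- mean(img$voxels[m])
  image_volume(out, img$spacing, img$origin)
}

#' Corrupt the interior of a displacement field
#'
#' Adds a smooth random perturbation to a ground-truth field, windowed so the
#' organ surface stays exact while the interior degrades — a stand-in for an
#' intensity-based registration that matches the organ surface but wanders on
#' a featureless interior. The perturbation is white noise smoothed to a
#' correlation length `corr_len_mm`, scaled to peak magnitude `amp_mm`, and
#' multiplied by a window that is 0 in a 2-voxel shell at the surface and
#' ramps to 1 over `ramp_mm` toward the interior. Deterministic given `seed`.
#'
#' @param u_gt ground-truth [displacement_field()].
#' @param organ organ [binary_mask()] on the same grid.
#' @param amp_mm peak perturbation magnitude in mm (0 returns `u_gt` as is).
#' @param corr_len_mm correlation length of the perturbation in mm.
#' @param seed RNG seed.
#' @param ramp_mm window ramp width in mm.
#' @return A [displacement_field()].
#' @export
corrupt_dvf <- function(u_gt, organ, amp_mm = 3, corr_len_mm = 8, seed = 1,
                        ramp_mm = 6) {
  stopifnot(inherits(u_gt, "bmdir_dvf"), inherits(organ, "bmdir_mask"))
  check_same_grid(u_gt, organ)
  if (amp_mm < 0) stop("amp_mm must be >= 0", call. = FALSE)
  if (amp_mm == 0) return(u_gt)
  if (corr_len_mm < max(u_gt$spacing))
    stop("corr_len_mm must be at least one voxel", call. = FALSE)
  d <- vol_dim(u_gt)
  sigma_vox <- corr_len_mm / u_gt$spacing
  p <- with_seed(seed, {
    lapply(1:3, function(c) smooth_gaussian(array(rnorm(prod(d)), d), sigma_vox))
  })
  # erosion-depth window: 0 within two voxel layers of the surface, then a
  # linear ramp to 1 over ramp_mm
  m <- organ$voxels > 0.5
  depth <- array(0, d)
  cur <- m
  n_layers <- 2L + as.integer(ceiling(ramp_mm / min(u_gt$spacing))) + 1L
  for (k in seq_len(n_layers)) {
    cur <- erode6(cur)
    depth[cur] <- depth[cur] + 1
  }
  ramp_layers <- ceiling(ramp_mm / min(u_gt$spacing))
  w <- pmin(pmax((depth - 2) / ramp_layers, 0), 1)
  mag <- sqrt((p[[1]] * w)^2 + (p[[2]] * w)^2 + (p[[3]] * w)^2)
  peak <- max(mag)
  if (peak <= 0) stop("window annihilates the perturbation (organ too small)",
                      call. = FALSE)
  s <- amp_mm / peak
  v <- u_gt$vectors
  for (c in 1:3) v[, , , c] <- v[, , , c] + s * w * p[[c]]
  displacement_field(v, u_gt$spacing, u_gt$origin)
}
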
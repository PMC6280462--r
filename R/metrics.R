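# Registration QA metric battery: Dice overlap, symmetric surface distances,
# Jacobian determinant maps, voxel-wise field discrepancy (TRD) and landmark
# target registration error (TRE).

#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)` by voxel counting on a shared grid.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "bmdir_mask"), inherits(b, "bmdir_mask"))
  check_same_grid(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) stop("both masks are empty", call. = FALSE)
  2 * sum(a$voxels * b$voxels) / (na + nb)
}

# physical coordinates (mm) of boundary voxels of a mask
.boundary_points <- function(mask) {
  b <- which(mask_boundary(mask))
  d <- vol_dim(mask)
  i <- (b - 1) %% d[1]
  j <- ((b - 1) %/% d[1]) %% d[2]
  k <- (b - 1) %/% (d[1] * d[2])
  cbind(mask$origin[1] + i * mask$spacing[1],
        mask$origin[2] + j * mask$spacing[2],
        mask$origin[3] + k * mask$spacing[3])
}

# for each row of p, the distance to the nearest row of q (exact, chunked
# over q to bound memory; row minima via pmin over column slices)
.nearest_distances <- function(p, q, chunk = 256L) {
  n <- nrow(p); m <- nrow(q)
  best <- rep(Inf, n)
  for (s in seq(1L, m, by = chunk)) {
    e <- min(m, s + chunk - 1L)
    qq <- q[s:e, , drop = FALSE]
    d2 <- outer(p[, 1], qq[, 1], "-")^2 +
          outer(p[, 2], qq[, 2], "-")^2 +
          outer(p[, 3], qq[, 3], "-")^2
    best <- pmin(best, do.call(pmin, lapply(seq_len(ncol(d2)), function(j) d2[, j])))
  }
  sqrt(best)
}

#' Hausdorff and mean surface distance between two masks
#'
#' Distances are measured between the boundary voxel sets (mask minus its
#' 6-connected erosion) in physical mm, anisotropic spacing respected, and
#' symmetrised: Hausdorff is the maximum of the two directed maxima, the mean
#' surface distance is the average of the two directed means.
#'
#' @param a,b nonempty [binary_mask()] objects on the same grid.
#' @return A list with `hausdorff_mm` and `mean_surface_distance_mm`.
#' @export
surface_distances <- function(a, b) {
  stopifnot(inherits(a, "bmdir_mask"), inherits(b, "bmdir_mask"))
  check_same_grid(a, b)
  if (sum(a$voxels) == 0 || sum(b$voxels) == 0)
    stop("surface distances require nonempty masks", call. = FALSE)
  pa <- .boundary_points(a); pb <- .boundary_points(b)
  dab <- .nearest_distances(pa, pb)
  dba <- .nearest_distances(pb, pa)
  list(hausdorff_mm = max(max(dab), max(dba)),
       mean_surface_distance_mm = (mean(dab) + mean(dba)) / 2)
}

# d/dx along one axis, central differences interior, one-sided at borders
.gradient_axis <- function(a, ax, h) {
  d <- dim(a)
  n <- d[ax]
  ip <- c(2:n, n); im <- c(1, 1:(n - 1))     # neighbour indices
  den <- rep(2 * h, n); den[1] <- h; den[n] <- h
  idx <- lapply(d, seq_len)
  idxp <- idx; idxp[[ax]] <- ip
  idxm <- idx; idxm[[ax]] <- im
  fp <- do.call(`[`, c(list(a), idxp, list(drop = FALSE)))
  fm <- do.call(`[`, c(list(a), idxm, list(drop = FALSE)))
  shape <- c(1, 1, 1); shape[ax] <- n
  (fp - fm) / array(rep(den, each = prod(d[seq_len(ax - 1)])), d)
}

#' Jacobian determinant map of a displacement field
#'
#' Computes `J(x) = det(I + grad u)` with spatial derivatives by central
#' differences in mm (one-sided at the grid border), plus mean/min/max/sd
#' summaries over an optional mask. Values below 1 indicate local contraction,
#' above 1 dilation, and non-positive values folding.
#'
#' @param dvf a [displacement_field()].
#' @param mask optional [binary_mask()] over which to summarise (default:
#'   whole grid).
#' @return A list of class `bmdir_jacobian`: `map` (an [image_volume()]),
#'   `mean`, `min`, `max`, `sd`.
#' @export
jacobian_map <- function(dvf, mask = NULL) {
  stopifnot(inherits(dvf, "bmdir_dvf"))
  d <- vol_dim(dvf)
  if (any(d < 3)) stop("jacobian_map needs at least 3 voxels per axis", call. = FALSE)
  G <- vector("list", 9)   # G[[3*(ax-1)+c]] = d u_c / d x_ax
  for (ax in 1:3) for (c in 1:3)
    G[[3 * (ax - 1) + c]] <- .gradient_axis(dvf$vectors[, , , c], ax, dvf$spacing[ax])
  F11 <- 1 + G[[1]]; F21 <- G[[2]]; F31 <- G[[3]]
  F12 <- G[[4]]; F22 <- 1 + G[[5]]; F32 <- G[[6]]
  F13 <- G[[7]]; F23 <- G[[8]]; F33 <- 1 + G[[9]]
  J <- F11 * (F22 * F33 - F23 * F32) -
       F12 * (F21 * F33 - F23 * F31) +
       F13 * (F21 * F32 - F22 * F31)
  sel <- if (is.null(mask)) TRUE else {
    check_same_grid(dvf, mask)
    mask$voxels > 0.5
  }
  vals <- if (isTRUE(sel)) as.numeric(J) else J[sel]
  structure(list(map = image_volume(J, dvf$spacing, dvf$origin),
                 mean = mean(vals), min = min(vals), max = max(vals),
                 sd = stats::sd(vals)),
            class = "bmdir_jacobian")
}

#' @export
print.bmdir_jacobian <- function(x, ...) {
  cat(sprintf("<bmdir_jacobian> mean %.4f, range [%.4f, %.4f], sd %.4f\n",
              x$mean, x$min, x$max, x$sd))
  invisible(x)
}

#' Extract axial-slice profiles from a Jacobian map
#'
#' Returns the anterior-posterior and lateral line profiles through a chosen
#' axial slice, for plotting against each other across methods.
#'
#' @param jac a `bmdir_jacobian` (or a scalar [image_volume()]).
#' @param k axial slice index (1-based; default: central slice).
#' @return A tibble with columns `direction`, `position_mm`, `jacobian`.
#' @export
jacobian_profile <- function(jac, k = NULL) {
  map <- if (inherits(jac, "bmdir_jacobian")) jac$map else jac
  d <- vol_dim(map)
  if (is.null(k)) k <- (d[3] + 1) %/% 2
  i_mid <- (d[1] + 1) %/% 2; j_mid <- (d[2] + 1) %/% 2
  tibble::tibble(
    direction = rep(c("lateral", "anterior-posterior"), times = c(d[1], d[2])),
    position_mm = c(map$origin[1] + (seq_len(d[1]) - 1) * map$spacing[1],
                    map$origin[2] + (seq_len(d[2]) - 1) * map$spacing[2]),
    jacobian = c(map$voxels[, j_mid, k], map$voxels[i_mid, , k]))
}

#' Target registration discrepancy between two displacement fields
#'
#' The per-voxel vector distance `||u_a - u_b||` in mm inside a mask, with a
#' cumulative histogram and the fraction of voxels above each threshold. The
#' default thresholds are the 1.5 mm and 2.0 mm reporting cuts.
#'
#' @param dvf_a,dvf_b [displacement_field()] objects on one grid.
#' @param mask [binary_mask()] defining the evaluation region.
#' @param thresholds_mm numeric thresholds for exceedance fractions.
#' @return A list of class `bmdir_trd`: `map` ([image_volume()]), `values`
#'   (in-mask magnitudes), `fractions_above` (named by threshold), `histogram`
#'   (tibble `threshold_mm`, `fraction_above`).
#' @export
trd <- function(dvf_a, dvf_b, mask, thresholds_mm = c(1.5, 2)) {
  stopifnot(inherits(dvf_a, "bmdir_dvf"), inherits(dvf_b, "bmdir_dvf"),
            inherits(mask, "bmdir_mask"))
  check_same_grid(dvf_a, dvf_b)
  check_same_grid(dvf_a, mask)
  dif <- dvf_a$vectors - dvf_b$vectors
  mag <- sqrt(dif[, , , 1]^2 + dif[, , , 2]^2 + dif[, , , 3]^2)
  vals <- mag[mask$voxels > 0.5]
  fr <- vapply(thresholds_mm, function(t) mean(vals > t), numeric(1))
  grid_t <- sort(unique(c(seq(0, max(vals) + 1e-9, length.out = 64), thresholds_mm)))
  hist_fr <- vapply(grid_t, function(t) mean(vals > t), numeric(1))
  structure(list(map = image_volume(mag, dvf_a$spacing, dvf_a$origin),
                 values = vals,
                 fractions_above = setNames(fr, paste0(thresholds_mm, "mm")),
                 histogram = tibble::tibble(threshold_mm = grid_t,
                                            fraction_above = hist_fr)),
            class = "bmdir_trd")
}

#' @export
print.bmdir_trd <- function(x, ...) {
  cat(sprintf("<bmdir_trd> mean %.3f mm, max %.3f mm; above thresholds: %s\n",
              mean(x$values), max(x$values),
              paste(sprintf("%s %.1f%%", names(x$fractions_above),
                            100 * x$fractions_above), collapse = ", ")))
  invisible(x)
}

#' Target registration error of landmarks under a displacement field
#'
#' For each pair, `TRE = ||(fixed + u(fixed)) - moving||` in mm with `u`
#' sampled trilinearly at the fixed point. Under a zero field this equals the
#' raw landmark separation.
#'
#' @param landmarks a [landmark_set()].
#' @param dvf a [displacement_field()] on the reference grid.
#' @return A list of class `bmdir_tre`: `per_landmark` (tibble `label`,
#'   `tre_mm`), `mean`, `sd`.
#' @export
tre <- function(landmarks, dvf) {
  stopifnot(inherits(dvf, "bmdir_dvf"))
  fx <- landmark_fixed(landmarks)
  d <- vol_dim(dvf)
  lo <- dvf$origin; hi <- dvf$origin + (d - 1) * dvf$spacing
  for (c in 1:3)
    if (any(fx[, c] < lo[c] - 1e-9 | fx[, c] > hi[c] + 1e-9))
      stop("landmark outside the displacement-field grid", call. = FALSE)
  u <- sample_dvf(dvf, fx)
  err <- sqrt(rowSums((fx + u - landmark_moving(landmarks))^2))
  structure(list(per_landmark = tibble::tibble(label = landmarks$label,
                                               tre_mm = err),
                 mean = mean(err), sd = if (length(err) > 1) stats::sd(err) else 0),
            class = "bmdir_tre")
}

#' @export
print.bmdir_tre <- function(x, ...) {
  cat(sprintf("<bmdir_tre> %d landmarks, mean %.3f +/- %.3f mm\n",
              nrow(x$per_landmark), x$mean, x$sd))
  invisible(x)
}

#' Full registration QA report
#'
#' Bundles the evaluation battery for one registration result: overlap and
#' surface distances between a warped structure and its reference, Jacobian
#' statistics of the field over the organ, voxel-wise discrepancy against a
#' comparison field, and landmark TRE. Components whose inputs are omitted
#' are skipped.
#'
#' @param structure_ref reference structure [binary_mask()].
#' @param structure_warped the structure mapped by the field under test.
#' @param dvf the field under test.
#' @param organ organ mask over which Jacobian/TRD are summarised.
#' @param dvf_compare comparison field for the TRD component.
#' @param landmarks optional [landmark_set()] for TRE.
#' @param thresholds_mm TRD reporting thresholds.
#' @return A list of class `bmdir_metrics`.
#' @export
metrics_report <- function(structure_ref = NULL, structure_warped = NULL,
                           dvf = NULL, organ = NULL, dvf_compare = NULL,
                           landmarks = NULL, thresholds_mm = c(1.5, 2)) {
  out <- list()
  if (!is.null(structure_ref) && !is.null(structure_warped)) {
    out$dsc <- dice(structure_ref, structure_warped)
    sd_ <- surface_distances(structure_ref, structure_warped)
    out$hausdorff_mm <- sd_$hausdorff_mm
    out$mean_surface_distance_mm <- sd_$mean_surface_distance_mm
  }
  if (!is.null(dvf)) out$jacobian <- jacobian_map(dvf, organ)
  if (!is.null(dvf) && !is.null(dvf_compare) && !is.null(organ))
    out$trd <- trd(dvf, dvf_compare, organ, thresholds_mm)
  if (!is.null(landmarks) && !is.null(dvf)) out$tre <- tre(landmarks, dvf)
  structure(out, class = "bmdir_metrics")
}

#' @export
print.bmdir_metrics <- function(x, ...) {
  if (!is.null(x$dsc))
    cat(sprintf("DSC %.4f | Hausdorff %.3f mm | MSD %.3f mm\n",
                x$dsc, x$hausdorff_mm, x$mean_surface_distance_mm))
  if (!is.null(x$jacobian))
    cat(sprintf("Jacobian mean %.4f [%.4f, %.4f]\n",
                x$jacobian$mean, x$jacobian$min, x$jacobian$max))
  if (!is.null(x$trd)) print(x$trd)
  if (!is.null(x$tre)) print(x$tre)
  invisible(x)
}

#' @export
tidy.bmdir_metrics <- function(x, ...) {
  rows <- list()
  add <- function(metric, value) rows[[length(rows) + 1]] <<-
    tibble::tibble(metric = metric, value = value)
  if (!is.null(x$dsc)) {
    add("dsc", x$dsc)
    add("hausdorff_mm", x$hausdorff_mm)
    add("mean_surface_distance_mm", x$mean_surface_distance_mm)
  }
  if (!is.null(x$jacobian)) {
    add("jacobian_mean", x$jacobian$mean)
    add("jacobian_min", x$jacobian$min)
    add("jacobian_sd", x$jacobian$sd)
  }
  if (!is.null(x$trd))
    for (nm in names(x$trd$fractions_above))
      add(paste0("trd_above_", nm), x$trd$fractions_above[[nm]])
  if (!is.null(x$tre)) {
    add("tre_mean_mm", x$tre$mean)
    add("tre_sd_mm", x$tre$sd)
  }
  do.call(rbind, rows)
}
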
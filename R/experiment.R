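# End-to-end multistage experiment: generate the phantom, corrupt the
# ground-truth field inside the organ (the stand-in for an intensity-based
# registration that is exact on the surface but unreliable on a featureless
# interior), refine biomechanically, and score both fields against the
# analytic ground truth with the full metric battery.

#' Configuration of the multistage refinement experiment
#'
#' @param phantom a [phantom_spec()].
#' @param corruption_amp_mm peak interior corruption magnitude in mm.
#' @param corruption_corr_len_mm corruption correlation length in mm.
#' @param refinement a [refinement_config()].
#' @param thresholds_mm TRD reporting thresholds in mm.
#' @param seed global experiment seed; every stochastic component derives its
#'   stream from it.
#' @param stages stage indices to run (default `0:n_stages`).
#' @return An object of class `bmdir_run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       corruption_amp_mm = 3,
                       corruption_corr_len_mm = 8,
                       refinement = refinement_config(),
                       thresholds_mm = c(1.5, 2),
                       seed = 1,
                       stages = NULL) {
  stopifnot(inherits(phantom, "bmdir_phantom_spec"),
            inherits(refinement, "bmdir_refinement_config"))
  structure(list(phantom = phantom,
                 corruption_amp_mm = corruption_amp_mm,
                 corruption_corr_len_mm = corruption_corr_len_mm,
                 refinement = refinement,
                 thresholds_mm = thresholds_mm,
                 seed = as.integer(seed),
                 stages = stages),
            class = "bmdir_run_config")
}

#' Run the multistage refinement experiment
#'
#' For every requested stage: build the phantom stage, corrupt the
#' ground-truth field (surface kept exact, interior degraded), refine it with
#' the biomechanical pipeline (organ mesh, elastic solve and factorisation
#' are built once and reused across stages), and evaluate corrupted and
#' refined fields against ground truth: tube overlap after warping (DSC,
#' Hausdorff, mean surface distance), Jacobian statistics inside the organ,
#' interior vector error, voxel-wise discrepancy (TRD) between the two
#' fields, and landmark TRE.
#'
#' @param cfg a [run_config()].
#' @param verbose print per-stage progress.
#' @return An object of class `bmdir_experiment`: `summary` (one tibble row
#'   per stage), `per_stage` (detail lists), `mesh_info`, `config`.
#' @export
run_experiment <- function(cfg = run_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "bmdir_run_config"))
  spec <- cfg$phantom
  stages <- if (is.null(cfg$stages)) 0:spec$n_stages else cfg$stages
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating phantom (%d stages)", length(stages))
  st <- generate_phantom(spec, stages = stages)
  organ <- st[[1]]$organ
  say("building organ mesh and elastic factorisation")
  target <- cfg$refinement$target_mean_tet_volume_mm3
  if (is.null(target)) target <- prod(organ$spacing)
  surf <- extract_surface(organ, cfg$refinement$smoothing_iters,
                          cfg$refinement$field_sigma)
  mesh <- tetrahedralize(surf, target, cfg$refinement$decimate_triangles)
  cache <- .make_refine_cache(mesh, organ, cfg$refinement)
  interior <- erode6(organ$voxels > 0.5)

  rows <- vector("list", length(st))
  detail <- vector("list", length(st))
  for (q in seq_along(st)) {
    s <- st[[q]]
    say("stage %d", s$stage)
    corrupted <- corrupt_dvf(s$dvf_gt, organ,
                             amp_mm = if (s$stage == 0) 0 else cfg$corruption_amp_mm,
                             corr_len_mm = cfg$corruption_corr_len_mm,
                             seed = cfg$seed + 7919L * s$stage)
    refined <- refine_on_mesh(corrupted, organ, mesh, cfg$refinement,
                              cache = cache)
    err <- function(dvf) {
      dd <- dvf$vectors - s$dvf_gt$vectors
      sqrt(dd[, , , 1]^2 + dd[, , , 2]^2 + dd[, , , 3]^2)[interior]
    }
    e_c <- err(corrupted); e_r <- err(refined)
    tube_warp_c <- warp_mask(s$tube_def, corrupted)
    tube_warp_r <- warp_mask(s$tube_def, refined)
    sd_c <- surface_distances(s$tube, tube_warp_c)
    sd_r <- surface_distances(s$tube, tube_warp_r)
    j_c <- jacobian_map(corrupted, organ)
    j_r <- jacobian_map(refined, organ)
    t_cr <- trd(corrupted, refined, organ, cfg$thresholds_mm)
    tre_c <- tre(s$landmarks, corrupted)
    tre_r <- tre(s$landmarks, refined)
    trig <- trigger_check(corrupted, refined, organ,
                          threshold_mm = cfg$thresholds_mm[1])
    rows[[q]] <- tibble::tibble(
      stage = s$stage,
      push_amplitude_mm = (s$stage / spec$n_stages) * spec$a_max,
      tube_dsc_before = dice(s$tube, s$tube_def),
      tube_dsc_corrupted = dice(s$tube, tube_warp_c),
      tube_dsc_refined = dice(s$tube, tube_warp_r),
      tube_hausdorff_corrupted_mm = sd_c$hausdorff_mm,
      tube_hausdorff_refined_mm = sd_r$hausdorff_mm,
      tube_msd_corrupted_mm = sd_c$mean_surface_distance_mm,
      tube_msd_refined_mm = sd_r$mean_surface_distance_mm,
      jacobian_mean_gt = s$jacobian_mean,
      jacobian_mean_corrupted = j_c$mean,
      jacobian_mean_refined = j_r$mean,
      jacobian_sd_corrupted = j_c$sd,
      jacobian_sd_refined = j_r$sd,
      err_median_corrupted_mm = stats::median(e_c),
      err_median_refined_mm = stats::median(e_r),
      err_p95_corrupted_mm = stats::quantile(e_c, 0.95, names = FALSE),
      err_p95_refined_mm = stats::quantile(e_r, 0.95, names = FALSE),
      trd_frac_above = list(t_cr$fractions_above),
      tre_mean_corrupted_mm = tre_c$mean,
      tre_mean_refined_mm = tre_r$mean,
      trigger_fraction = trig$fraction_above,
      trigger_flag = trig$flag)
    detail[[q]] <- list(stage = s$stage, trd = t_cr,
                        tre_corrupted = tre_c, tre_refined = tre_r,
                        landmarks = s$landmarks)
  }
  structure(list(summary = do.call(rbind, rows),
                 per_stage = detail,
                 mesh_info = list(n_nodes = nrow(mesh$nodes),
                                  n_tets = nrow(mesh$tets),
                                  mean_tet_volume_mm3 = mean(tet_volumes(mesh)),
                                  voxel_volume_mm3 = prod(organ$spacing)),
                 config = cfg),
            class = "bmdir_experiment")
}

#' @export
print.bmdir_experiment <- function(x, ...) {
  cat(sprintf("<bmdir_experiment> %d stages, mesh %d nodes / %d tets\n",
              nrow(x$summary), x$mesh_info$n_nodes, x$mesh_info$n_tets))
  print(x$summary[, c("stage", "tube_dsc_corrupted", "tube_dsc_refined",
                      "err_median_corrupted_mm", "err_median_refined_mm",
                      "jacobian_mean_refined")])
  invisible(x)
}

#' @export
tidy.bmdir_experiment <- function(x, ...) x$summary

#' @export
glance.bmdir_experiment <- function(x, ...) {
  s <- x$summary[x$summary$stage > 0, , drop = FALSE]
  tibble::tibble(
    n_stages = nrow(s),
    mean_dsc_gain = mean(s$tube_dsc_refined - s$tube_dsc_corrupted),
    mean_median_error_reduction = mean(1 - s$err_median_refined_mm /
                                           s$err_median_corrupted_mm),
    mean_jacobian_sd_ratio = mean(s$jacobian_sd_refined / s$jacobian_sd_corrupted),
    n_nodes = x$mesh_info$n_nodes, n_tets = x$mesh_info$n_tets)
}

#' Stage curves for a multistage experiment
#'
#' Plots tube DSC, median interior error and organ Jacobian statistics per
#' deformation stage for the corrupted (initial) and refined fields —
#' the summary figures of the multistage evaluation.
#'
#' @param object a `bmdir_experiment`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bmdir_experiment <- function(object, ...) {
  s <- object$summary
  long <- rbind(
    data.frame(stage = s$stage, panel = "tube DSC", field = "initial (corrupted)",
               value = s$tube_dsc_corrupted),
    data.frame(stage = s$stage, panel = "tube DSC", field = "refined",
               value = s$tube_dsc_refined),
    data.frame(stage = s$stage, panel = "median interior error (mm)",
               field = "initial (corrupted)", value = s$err_median_corrupted_mm),
    data.frame(stage = s$stage, panel = "median interior error (mm)",
               field = "refined", value = s$err_median_refined_mm),
    data.frame(stage = s$stage, panel = "organ Jacobian SD",
               field = "initial (corrupted)", value = s$jacobian_sd_corrupted),
    data.frame(stage = s$stage, panel = "organ Jacobian SD",
               field = "refined", value = s$jacobian_sd_refined))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$value,
                                     colour = .data$field)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "deformation stage", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cumulative TRD histogram plot
#'
#' The cumulative fraction of organ voxels whose discrepancy between two
#' fields exceeds each threshold, one curve per stage.
#'
#' @param experiment a `bmdir_experiment`.
#' @return A ggplot object.
#' @export
plot_trd_histogram <- function(experiment) {
  dfs <- lapply(experiment$per_stage, function(d) {
    if (d$stage == 0) return(NULL)
    cbind(stage = d$stage, as.data.frame(d$trd$histogram))
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold_mm,
                                   y = .data$fraction_above,
                                   colour = factor(.data$stage))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "TRD threshold (mm)", y = "fraction of organ voxels above",
                  colour = "stage") +
    ggplot2::theme_minimal()
}

#' Axial Jacobian profile plot for one displacement field
#'
#' @param dvf a [displacement_field()].
#' @param mask optional organ mask for the summary window.
#' @param k axial slice (default central).
#' @return A ggplot object.
#' @export
plot_jacobian_profile <- function(dvf, mask = NULL, k = NULL) {
  prof <- jacobian_profile(jacobian_map(dvf, mask), k)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position_mm, y = .data$jacobian)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "position (mm)", y = "Jacobian determinant") +
    ggplot2::theme_minimal()
}

#' Write an experiment summary to JSON
#'
#' Serialises the per-stage summary table, mesh information and headline
#' aggregates (a machine-readable run manifest).
#'
#' @param experiment a `bmdir_experiment`.
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_experiment_json <- function(experiment, path) {
  s <- experiment$summary
  s$trd_frac_above <- lapply(s$trd_frac_above, as.list)
  payload <- list(summary = s,
                  mesh = experiment$mesh_info,
                  aggregate = as.list(glance(experiment)),
                  seed = experiment$config$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
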
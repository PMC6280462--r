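# bmdir — biomechanical refinement of deformable registration fields

Deformable image registration (DIR) driven by image intensity alone cannot
constrain the displacement field *inside* organs that look homogeneous in the
image: the interior is then shaped by a generic smoothness regulariser rather
than by physics, which matters whenever the field is used voxel-wise (dose
accumulation, response mapping) and not just for contour propagation. `bmdir`
is an R package for radiotherapy/medical-imaging researchers that refines the
interior of any initial displacement vector field (DVF) within an organ by
solving a physical model, and ships the quality-assurance metric battery and
a synthetic multistage deformable phantom used to validate it.

## The method

Given a reference image, an organ mask and an initial DVF `u₀` (pull-back
convention: the field at fixed-space point `x` maps it to moving-space point
`x + u(x)`):

1. extract the organ surface from the mask (marching-tetrahedra iso-surface,
   Taubin smoothing, volume-preserving rescale);
2. fill it with a tetrahedral mesh whose mean element volume is slightly
   below the image voxel volume;
3. sample `u₀` trilinearly at the surface nodes and impose those vectors as
   Dirichlet boundary conditions on an isotropic linear-elastic solid
   (defaults ν = 0.40, E = 0.27 MPa; under full-surface Dirichlet conditions
   the solution is exactly invariant to E);
4. solve `K u = f` for the interior nodes (sparse Cholesky, relative
   residual ≤ 1e-8) and scatter the nodal solution back to the organ voxels
   by barycentric interpolation — voxels outside the organ keep `u₀`.

Affine fields pass through the entire pipeline exactly (the FEM patch test),
which anchors the test suite. Evaluation uses the standard battery: Dice
overlap, symmetric Hausdorff and mean surface distance, Jacobian determinant
maps `det(I + ∇u)`, voxel-wise field discrepancy (TRD) with cumulative
histograms, and landmark target registration error (TRE).

Because no reference images are distributed, the package also generates a
synthetic multistage phantom: an ellipsoidal organ with a bright internal
tube, deformed through ten graded stages by a smooth balloon-like radial
push with an analytic ground-truth DVF, plus a "masked" homogeneous-interior
image variant and a corruption model that degrades the field interior while
keeping the surface exact — the failure mode the refinement is designed to
repair.

## Worked example

```r
library(bmdir)

cfg  <- run_config(seed = 1, stages = c(0, 5, 10))   # three-stage run
exp_ <- run_experiment(cfg)
exp_
#> <bmdir_experiment> 3 stages, mesh 10245 nodes / 46080 tets
#> # A tibble: 3 × 6
#>   stage tube_dsc_corrupted tube_dsc_refined err_median_corrupted_mm
#>   <dbl>              <dbl>            <dbl>                   <dbl>
#> 1     0              1                1                       0
#> 2     5              0.772            0.995                   0.743
#> 3    10              0.855            0.976                   0.723

glance(exp_)
#> # A tibble: 1 × 6
#>   n_stages mean_dsc_gain mean_median_error_redu…¹ mean_jacobian_sd_ratio ...
#> 1        2         0.172                    0.705                  0.230
```

Reading the numbers: at stage 0 (no deformation) everything is perfect by
construction. At the deformed stages the corrupted initial field warps the
internal tube back onto its reference with Dice 0.77–0.86; the
biomechanically refined field raises that to 0.98–0.99, cuts the median
interior vector error against the analytic ground truth by ~70%
(`mean_median_error_reduction = 0.705`), and smooths the Jacobian map (the
refined-to-corrupted Jacobian SD ratio is 0.23) — the elastic interior is
both closer to the truth and more physically plausible. `autoplot(exp_)`
draws the per-stage curves, `plot_trd_histogram(exp_)` the cumulative
discrepancy histograms.

Individual steps are available as plain functions operating on
`image_volume` / `binary_mask` / `displacement_field` containers
(NIfTI/NRRD I/O via `read_volume()` / `write_volume()`):

```r
organ   <- read_volume("organ.nii.gz", "mask")
u0      <- read_volume("dvf_init.nii.gz", "dvf")
refined <- refine(u0, organ)                       # the whole pipeline
trigger_check(u0, refined, organ)                  # large-discrepancy flag
```

A thin CLI covering the same steps (phantom generation, meshing, refinement,
metrics, the full experiment) is installed at
`system.file("cli/bmdir", package = "bmdir")`.

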
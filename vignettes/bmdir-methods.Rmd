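---
title: "Biomechanical refinement of registration fields: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanical refinement of registration fields: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intensity-driven deformable image registration (DIR) estimates a displacement
vector field (DVF) — one 3-vector per voxel of a reference grid — by
optimising image similarity under generic smoothness regularisation. On
organs whose interior is nearly homogeneous in the imaging modality at hand
(prostate on CT, parotid on masked MR, soft tissue on CBCT), the similarity
term carries no information inside the organ: the interior of the field is
determined by the regulariser, which is not a physical model. The organ
*surface*, by contrast, usually has enough contrast to be matched well, and
contour-constrained registration can guarantee it.

`bmdir` implements the biomechanical refinement of such a field: keep the
surface correspondence of the initial registration, discard its interior, and
recompute the interior as the solution of a linear-elastic boundary-value
problem. The organ becomes an isotropic elastic solid; the surface
displacements (sampled trilinearly from the initial DVF at the mesh surface
nodes) are Dirichlet boundary conditions; the interior nodal displacements
follow from equilibrium with no body force; and the nodal solution is
scattered back to the voxel grid by barycentric interpolation inside each
tetrahedron. Voxels outside the organ keep the initial field.

## The elastic model and its assumptions

Small-strain isotropic linear elasticity with uniform material parameters:
Poisson ratio $\nu = 0.40$ and Young's modulus $E = 0.27$ MPa by default,
standard soft-tissue values for prostate-like organs. Two properties of the
pure-Dirichlet formulation matter in practice:

* **$E$ cancels exactly.** Both the stiffness matrix and the boundary-driven
  right-hand side are linear in $E$, so the displacement solution is
  invariant to it. Only $\nu$ influences the interior field. This is why
  material-property uncertainty is benign here; `scale_invariance_check()`
  demonstrates it on any model.
* **Affine fields are exact solutions.** Homogeneous elasticity with no body
  force reproduces any affine displacement exactly (the patch test). This
  gives a machine-precision end-to-end correctness check through surface
  extraction, meshing, solving and scattering, which the test suite runs on
  pipeline-generated meshes.

The element is the 4-node constant-strain tetrahedron (`C3D4`). At
$\nu = 0.40$ volumetric locking is mild; no locking mitigation is applied,
and $\nu \ge 0.45$ should be used with caution (documented limitation). The
reduced system (Dirichlet dofs eliminated, their contribution moved to the
right-hand side) is symmetric positive definite; it is solved by sparse
Cholesky factorisation up to $2\times10^5$ unknowns and by
Jacobi-preconditioned conjugate gradients beyond, to a relative residual of
$10^{-8}$. The factorisation is cached and reused across repeated solves on
one mesh (the multistage experiment solves one geometry under many boundary
conditions).

## Surface extraction and meshing

The organ surface is the 0.5 iso-surface of the Gaussian-smoothed
(σ = 1 voxel) binary mask, extracted with a **marching-tetrahedra** variant
of marching cubes: each lattice cube is split into six tetrahedra around a
fixed main diagonal, so cut faces agree between neighbouring cells and the
triangulation is watertight and consistently wound by construction, with no
ambiguous-case table. Taubin smoothing (λ = 0.5, μ = −0.53, 10 iterations)
removes lattice texture with little shrinkage. Because smoothing an
indicator moves its mid-level set inward at a rate proportional to local
curvature, the extracted surface is finally rescaled about its centroid so
the enclosed volume equals the voxel-counted mask volume — a
volume-preserving smoothing correction that keeps organ volume conservation
exact by construction while leaving vertices well within half a voxel of
their uncorrected positions.

Volume meshing uses a star-shaped "onion" construction rather than a
constrained Delaunay code: the input triangulation is kept verbatim as the
mesh boundary; nested copies of it, scaled toward the volume centroid at
fractions $t_k = (k/n)^{3/4}$, are connected by prism frusta split
face-consistently through their centroids (quad diagonals chosen by the
smallest global vertex id, so neighbouring prisms agree); the innermost
cavity is fanned to the centroid. Consequences:

* the summed element volume equals the divergence-theorem volume of the
  input surface to round-off (an analytic cube meshes to volume 1 within
  $10^{-6}$);
* the mesh conforms and all elements are positively oriented whenever the
  region is star-shaped about its centroid — always true for the
  ellipsoid-like organs this package targets, and checked at run time with a
  clear error otherwise (the documented limitation of this mesher);
* surface nodes *are* input-surface points exactly.

Surfaces finer than ~6000 triangles are first remeshed by casting icosphere
directions from the centroid onto the surface (exact ray-triangle
intersection, so remeshed vertices lie exactly on the input surface); this
bounds the boundary resolution near 5000 triangles and keeps system sizes at
desk scale. The layer count is then chosen so the mean element volume does
not exceed the requested target — by default the image voxel volume,
following the sizing rule that elements should be slightly smaller than a
voxel for interpolation accuracy. `quality_metrics()` reports per-element
radius ratio, edge ratio, min/max dihedral angle, the volume–edge-length
measure, aspect ratio and signed volume; all hit their closed-form values on
the regular tetrahedron and are invariant under rigid motion.

## Scattering and boundary policy

Each organ voxel centre is located in its containing tetrahedron through an
axis-aligned bounding-box index with a $-10^{-9}$ barycentric containment
tolerance, then the four nodal vectors are interpolated barycentrically
("scattered linear interpolation"). Barycentric interpolation is exact on
linear fields, which the tests verify to $10^{-10}$. Mask voxels that fall
outside every element (the thin partial-volume shell between the smoothed
surface and the blocky mask) are extrapolated from the nearest node's best
incident element when they lie within one voxel of the mesh, and otherwise
take the nearest node's value; both cases are counted and reported. The
refined field replaces the initial one with a hard switch at the mask
boundary — the surface agreement of the boundary conditions keeps the seam
small — and an optional one-voxel linear feathering (`feather_voxels = 1`)
is available but off by default.

## The synthetic multistage phantom

No reference images are distributed with the package; every experiment runs
on a synthetic analogue of a multistage deformable pelvic phantom:

* an ellipsoidal organ (default semi-axes 22.1 × 19.25 × 25.35 mm, i.e.
  44.2 × 38.5 × 50.7 mm across) containing a bright tube (radius 3 mm along
  the organ axis) inside a 64³ grid at 1 mm isotropic spacing — the organ
  would not fit a 64³ box at an anisotropic 0.5 × 0.5 × 2 mm resolution, so
  the default grid trades voxel anisotropy for coverage; `resample()`
  supports anisotropic grids throughout;
* MR-like texture: band-limited Gaussian random blobs inside the organ over
  a darker background, plus the bright tube; `mask_interior()` produces the
  feature-poor variant by overriding the organ interior (after a one-voxel
  erosion, so boundary contrast survives) with the organ's mean intensity;
* deformation by a smooth balloon-like radial push
  $u(x) = a\,(r/\sigma)\,e^{(1-(r/\sigma)^2)/2}\,\hat r$ about a centre
  below the organ, with stage amplitudes on a linear schedule
  $a_i = (i/n)\,a_{\max}$ (defaults: σ = 12 mm, centre 16 mm below the
  organ pole, $a_{\max}$ = 8 mm, 10 stages). The form is analytic
  everywhere (no direction singularity at the centre), peaks at $r=\sigma$,
  and the defaults were fixed by a forward scan of the analytic Jacobian:
  they give a strictly decreasing mean organ Jacobian across stages with
  the minimum Jacobian safely positive. A single smooth radial push is
  necessarily *surface-dominant*: net compression requires most of the
  organ beyond $1.73\sigma$, which confines large displacements to the
  organ's near side (the physical phantom's core compression comes from
  container confinement, which is not emulated). Interior-accuracy stress
  therefore comes from the corruption model below, not from core motion;
* deformed images are produced by resampling the reference texture at the
  inverse map, so the analytic field is *exactly* the pull-back DVF the rest
  of the code expects. The inverse is computed by fixed-point iteration
  ($\psi \leftarrow y - u(\psi)$, tolerance $10^{-3}$ mm, 50 iterations),
  with a damped fallback ($\omega = 0.5$) for the small region near the push
  centre where $\lVert\nabla u\rVert > 1$ makes the plain iteration
  non-contractive even though the map itself stays bijective;
* `corrupt_dvf()` emulates the failure mode being studied — an initial
  registration that is exact on the surface but wanders on a featureless
  interior — by adding smoothed white noise (correlation length 8 mm,
  peak 3 mm by default) windowed to zero within two voxel layers of the
  organ surface and ramping to full strength over 6 mm toward the interior.
  It is deterministic given its seed.

What the phantom does **not** emulate: imaging physics (noise spectra, bias
fields, partial volume beyond trilinear sampling), container confinement,
multi-organ anatomy, and non-smooth or sliding deformation. Passing the
recovery experiment therefore shows that the elastic interior reconstruction
recovers smooth surface-driven deformations from corrupted interiors — not
that it handles discontinuous motion or real-image artefacts.

## Conventions and numerical choices

* Internal length unit is mm everywhere; voxel model is 0-based indices at
  voxel centres; the axis order is x-fastest, and file orientations
  (axis-aligned flips/permutations) are normalised on read. Oblique
  orientation matrices are rejected.
* The DVF convention is pull-back on the reference grid: the field value at
  fixed-space $x$ points to the corresponding moving-space point $x + u(x)$;
  warping resamples the moving image there. This is the only convention
  consistent with both mask propagation onto the reference and surface
  boundary conditions on the reference organ.
* DVF sampling clamps to the grid edge (surface nodes may sit on, or round
  just beyond, the boundary); image warping uses a fill value (default 0)
  instead.
* Mask warping and mask resampling are trilinear followed by a 0.5
  threshold: deterministic and stable for overlap metrics.
* Surface distance metrics use the symmetric definitions — Hausdorff as the
  maximum of the two directed maxima, mean surface distance as the mean of
  the two directed means — over boundary voxel sets (mask minus 6-connected
  erosion) with anisotropic spacing respected; distances are exact pairwise
  Euclidean minima, identical to the brute-force definition.
* Jacobian maps use central differences in mm (one-sided at the grid
  border): $J = \det(I + \nabla u)$, below 1 contraction, above 1 dilation,
  non-positive folding.
* Landmark TRE samples the field trilinearly at the fixed point:
  $\mathrm{TRE} = \lVert (p_f + u(p_f)) - p_m \rVert$.

## Problem sizes

The default experiment meshes the 64³ phantom organ at sub-voxel mean
element volume (about 46k tetrahedra on 10k nodes), factorises once, and
re-solves the ten stages against the cached factorisation; the whole
ten-stage run, including metric evaluation, completes in a few minutes on
one CPU. The tabulated per-stage results (`bmdir_experiment$summary`) are
what `scripts/acceptance.R` re-computes and serialises.

## Interfaces

The package is function-first: S3 containers wrap dense arrays and meshes
(the natural shapes of volumetric data), while every tabular result —
quality tables, metric reports, TRE tables, experiment summaries — is a
tibble, fitted objects have `tidy()`/`glance()` methods, and
`autoplot()`/`plot_*()` give ggplot2 views of experiments, TRD histograms
and Jacobian profiles. A thin command-line front end
(`system.file("cli/bmdir", package = "bmdir")`) exposes the phantom
generator, mesher, refiner, metric battery and the full experiment as
subcommands for shell pipelines, with NIfTI/NRRD volumes, CSV landmarks,
YAML configs and JSON reports at the boundaries.
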
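Package: bmdir
Title: Biomechanical Refinement of Deformable Image Registration Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines the interior of a deformable image registration (DIR)
    displacement vector field within an organ by solving a linear-elastic
    tetrahedral finite-element problem driven by surface-node displacements
    sampled from the initial field. Includes containers and I/O for 3-D image
    volumes, binary masks and displacement fields (NIfTI, NRRD), surface
    extraction and quality-checked tetrahedral meshing, a registration QA
    metric battery (Dice, Hausdorff and mean surface distance, Jacobian
    determinant maps, voxel-wise field discrepancy, landmark target
    registration error), and a synthetic multistage deformable phantom with
    analytic ground-truth deformations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    tibble,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
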
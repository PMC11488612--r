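Package: glymphalps
Title: DTI-ALPS Glymphatic Index, Voxel-Based Morphometry and Bootstrap
    Mediation on Synthetic Neuroimaging Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the diffusion-tensor-image analysis along the
    perivascular space (DTI-ALPS) index from directional diffusivity maps,
    fits diffusion tensors from diffusion-weighted stacks, runs
    mass-univariate voxelwise general linear models on smoothed modulated
    gray-matter maps with cluster-extent thresholding and max-statistic
    permutation family-wise error control, extracts spherical gray-matter
    seeds at cluster peaks, and tests whether seed gray-matter volume
    mediates the ALPS-cognition relationship via Preacher-Hayes
    bias-corrected bootstrap mediation. A synthetic two-group cohort
    generator with a configurable structural mediation model makes the
    whole chain testable end to end without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
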
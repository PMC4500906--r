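Package: sgdm
Title: Surface-Guided Mapping of Diffusion MRI onto the Cortical Surface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects mean-diffusivity (MD) volumes onto cortical surface
    meshes while compensating for the geometric misalignment that EPI
    distortion introduces between diffusion-weighted and structural spaces.
    Implements nearest-neighbour and trilinear volume-to-vertex sampling,
    surface-guided diffusion mapping (SGDM) that relocates the GM/CSF
    boundary along per-vertex intensity profiles before sampling at
    mid-cortical depth, a two-compartment partial-volume correction for CSF
    contamination of cortical MD, a log-linear least-squares diffusion
    tensor fit, vertex-wise paired statistics with surface smoothing, and a
    fully synthetic layered-brain phantom with known ground truth for
    validating the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
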
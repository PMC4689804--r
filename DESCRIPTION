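Package: histotract
Title: Structure-Tensor Fiber Orientation Analysis and Histology-Based
    Tractography of Stained Brain Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting fiber orientation from digitalized stained
    histological sections of the developing brain. Computes per-pixel 2D
    structure tensors, orientation, coherency and two-dimensional fractional
    anisotropy maps, renders hue-saturation-brightness orientation images,
    embeds the 2D tensors as pseudo-3D diffusion tensors exported to 4D NIfTI,
    builds brain and high-anisotropy seed masks, and performs deterministic
    fourth-order Runge-Kutta streamline tractography with probabilistic
    nearest-neighbor interpolation, writing colored streamlines as legacy VTK
    polydata. Includes a synthetic phantom generator (stripe, arc, laminar
    wall, punctate and crossing-fiber textures) with ground truth so every
    stage of the pipeline can be validated without slide-scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
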
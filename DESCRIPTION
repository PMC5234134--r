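Package: sinomar
Title: Sinogram-Inpainting Metal Artifact Reduction for Fan-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and correction of metal artifacts in two-dimensional
    fan-beam X-ray computed tomography. Provides a ray-driven fan-beam
    forward projector and filtered backprojection for a flat equispaced
    detector, seeded jaw-like and hip-like phantom generators with metal
    inserts, a Poisson photon-statistics acquisition simulator, tissue-
    classified prior images, the linear-interpolation (LI) and normalized
    (NMAR) sinogram-inpainting baselines, and a Gaussian-diffusion
    sinogram-inpainting algorithm with momentum acceleration and
    projection-onto-convex-sets data consistency. Image quality is assessed
    with signal-to-noise ratio, normalized mean absolute deviation, and
    region-of-interest statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
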
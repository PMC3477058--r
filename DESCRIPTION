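Package: retinodiag
Title: Automated Retinal Screening from Fundus and OCT Images
Version: 0.1.0
Authors@R: person("Retinodiag", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Morphology-based detection of diabetic-retinopathy lesions
    (optic disc, vessels, exudates, fovea, microaneurysms and hemorrhages)
    and five-level severity grading from color fundus photographs, plus
    glaucoma screening from OCT B-scans via eight-neighbor anisotropic
    diffusion, greedy active-contour boundary refinement and retinal
    nerve-fiber-layer thickness estimation. Includes seeded synthetic
    phantom generators with exact ground truth for every stage, plain-text
    raster (PNM) input/output, and command-line pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
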
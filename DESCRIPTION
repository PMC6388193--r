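Package: veneerfit
Title: Digital Design and Fit Assessment of Temporary Dental Veneers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Digital workflow for designing temporary veneers that restore
    autotransplanted premolars to incisor shape, together with two fit
    validation protocols: marginal gap measurement on calibrated margin
    images and internal adaptation from micro-CT volumes via indirect gap
    segmentation and 3D local thickness mapping. Includes semi-interactive
    livewire tooth segmentation (gradient-cost minimal paths, variational
    implicit-surface reconstruction from orthogonal contours), voxel-backed
    mesh Boolean CAD operations (crown isolation, mirroring, subtraction,
    undercut blockout, edge beveling), gap summary statistics with one-way
    ANOVA, and a synthetic tooth/veneer phantom generator with ground truth
    so every stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
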
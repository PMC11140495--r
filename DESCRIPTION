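Package: latticepick
Title: Lattice-Aware Particle Picking for Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("latticepick", "developers", email = "latticepick@example.org",
           role = c("aut", "cre"))
Description: Iterative template-matching tracing of flexible 1D-3D particle
    lattices in cryo-electron tomograms ("auto expansion"): candidate
    generation from seed particles via a user-defined transition list, masked
    normalized cross-correlation alignment on a constrained pose grid,
    iterative bookkeeping with on-disk caching and threshold regathering,
    geometry-based particle cleaning (neighbor count and averaged inter-axis
    tilt), segmentation-label generation and clustering-based coordinate
    retrieval, and STAR/MRC/point-file plumbing. Ships a synthetic-data module
    (hexagonal lattices on planes and spheres, filament repeats, density
    rendering of oriented templates) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
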
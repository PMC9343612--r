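Package: tomostream
Title: Streaming Tilt-Series Alignment and Real-Time Tomographic
    Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless pipeline for single-axis electron tomography with
    live acquisition support. Provides a matched forward/adjoint
    parallel-beam projector, tilt-series alignment by center of mass and
    cross-correlation with rotation-axis offset estimation, and three
    reconstruction engines: weighted back projection emitted slice by
    slice, SIRT as Lipschitz-stepped gradient descent on the projection
    residual, and total-variation minimization with a linearly decaying
    dampening envelope. A polling directory watcher appends newly
    acquired projections to a running reconstruction without restarting
    it and publishes consistent intermediate snapshots under a
    triple-buffer memory contract. A synthetic module generates phantoms
    (spheres, chiral helix, periodic lattice, disc, impulse) and
    simulates acquisition with Poisson dose, missing wedge, shift jitter
    and axis offset so the whole pipeline is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
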
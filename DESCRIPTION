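Package: tissuessa
Title: Multilevel Event-Driven Simulation of Signaling Cells in Growing
    Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Couples spatial-stochastic single-cell models of the
    Notch-Delta-Reporter lateral-inhibition pathway, discretized on an
    unstructured mesh and sampled by the Next Subvolume Method, to an
    on-lattice cell-population model in which over-occupied voxels source
    a discrete-Laplacian pressure field that drives cell movement and
    nutrient-limited proliferation. Cell-to-cell signaling acts through
    junctional contacts and through cellular protrusions parameterized by
    length, direction and angular width. Both layers run in continuous
    time by Gillespie-style event-driven algorithms and are coupled with
    an adaptive split-step scheme that freezes signals over short time
    chunks; growth trajectories can be recorded as event logs and
    replayed deterministically under the full molecular model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
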
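Package: cerebsim
Title: Simulation of MEG/EEG Signal Cancelation on Folded Cortical Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how cortical and cerebellar folding attenuates
    magnetoencephalography (MEG) and electroencephalography (EEG) signals.
    Generates synthetic folded source surfaces embedded in a three-shell
    spherical head, synthesizes magnetometer, planar-gradiometer, and
    electrode arrays, computes current-dipole lead fields with analytic
    sphere models or a boundary-element method with linear collocation,
    and runs Monte Carlo simulations of distributed dipoles and spatially
    coherent patches to estimate the conservation factor (net over absolute
    signal), physiologically scaled signal norms, and per-vertex sensitivity
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
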
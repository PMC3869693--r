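Package: waterperm
Title: Water Permeability Analysis for Membrane Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators and converters for water permeation through
    narrow membrane channels. Computes single-channel permeability
    coefficients from particle trajectories (event-counting diffusional
    permeability and collective-diffusion osmotic permeability), axial
    profiles along the pore (density, potential of mean force by
    Boltzmann inversion, dipole order parameter, hydrogen-bond counts),
    and macroscopic permeabilities from stopped-flow relaxation traces
    (osmotic and diffusional water permeability, solute permeabilities,
    per-channel unit permeabilities, single-file water counts and
    Arrhenius activation energies). Includes stochastic single-file
    pore simulators (discrete vacancy hopping and Brownian dynamics
    with hard-core exclusion) for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
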
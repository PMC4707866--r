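Package: clotlysis
Title: Multi-Physics Simulation of Fibrinolytic Clot Dissolution Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Continuum modelling of thrombolysis: well-mixed fibrinolysis
    reaction and surface-adsorption kinetics (tPA, plasminogen, plasmin,
    antiplasmin) coupled to a fibrin microstructure model (fibre radius,
    voidage, binding-site density, Davies permeability), a one-dimensional
    diffusion-limited reaction-transport tier with lysis-front tracking, and
    a two-dimensional volume-averaged porous-medium flow tier
    (Stokes-Brinkman with Darcy resistance) coupled to species
    advection-diffusion-reaction. Simulates the full lytic process of an
    occlusive clot in a channel, from diffusion-limited lysis through
    recanalization to convection-dominated mural-clot lysis, with
    breakthrough-ratio and recirculation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
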
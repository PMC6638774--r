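Package: polcompass
Title: Simulation of the Insect Polarised-Light Compass
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end simulation of a celestial compass based on skylight
    polarisation, as used by navigating insects such as desert ants. Provides
    a Rayleigh sky-dome model with a solar ephemeris, a biomimetic dorsal-rim
    sensor array of polarisation-opponent units, an eight-neuron population
    compass with tilt gating and confidence-driven time compensation,
    evaluation protocols over tilt and disturbance ensembles, a closed-loop
    path-integration agent simulation on even and uneven terrain, and
    simulated electrophysiology of compass-neuron tuning under a rotating
    polariser versus a rotating natural sky.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
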
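Package: fluxpulse
Title: Detection and Bias Correction of Rain-Induced Soil CO2 Pulses in
    Eddy-Covariance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying, characterizing and bias-correcting
    rain-induced soil CO2 emission pulses (the Birch effect) in half-hourly
    dryland eddy-covariance records. Reads ONEFlux/FLUXNET-style tables,
    computes evaporative-fraction rewetting indices, screens and catalogs
    pulse events, fits first-order kinetic decay curves per event and per
    site, implements the night-time (Lloyd-Taylor) flux-partitioning
    baseline, and applies a decaying multiplicative correction that anchors
    ecosystem respiration on the first pulse day to the observed maximum net
    ecosystem exchange. Includes a random-forest pulse-event detector with
    start-date scoring, Lindeman-Merenda-Gold relative-importance analysis of
    spatial drivers, and a synthetic flux-tower generator with known
    respiration/photosynthesis partitioning for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
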
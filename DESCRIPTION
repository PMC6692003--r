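Package: synchroburst
Title: Synchronous-Burst Detection and Metabolically Coupled Spiking-Network
    Simulation for Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying network-wide synchronous bursting in cultured
    excitatory neuronal networks recorded on multi-electrode arrays (MEAs).
    Provides S4 containers and plain-text I/O for per-electrode spike-time
    recordings; a two-stage synchronous-burst detector reporting synchronous
    bursts per minute (SBPM); a conductance-based spiking-network simulator of
    400 simplified Hodgkin-Huxley neurons on a square lattice with
    distance-dependent random connectivity, single-pool synaptic vesicle
    depression, and glucose-gated modulation of vesicle recovery; a synthetic
    MEA recording generator with planted ground-truth bursts for detector
    validation; and condition-level summary statistics (mean +/- SEM, Student's
    t-tests) with an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
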
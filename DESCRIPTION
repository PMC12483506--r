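Package: lspsmap
Title: Analysis of Laser-Scanning Photostimulation Synaptic Input Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping functional corticostriatal connectivity with
    laser-scanning photostimulation (LSPS) glutamate uncaging. Converts per-site
    voltage-clamp sweeps into synaptic input maps and binary connectivity maps
    (3-SD detection threshold with a repetition-consistency rule), computes
    connectivity-pattern geometry (clusters on the collapsed profile, cortical
    column counts, input fields and gaps, layer-wise EPSC sums), centers of mass
    and cohort topography summaries, pairwise map-overlap statistics for cells
    recorded in the same slice, excitation-profile metrics, and a Monte-Carlo
    estimate of synapse loss from slice truncation under a spherical
    dendritic-field model. Includes a synthetic-data generator with known ground
    truth so the full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
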
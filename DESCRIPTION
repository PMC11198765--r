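Package: panoscan
Title: Virtual Pan-Tilt Panoramic LiDAR Scanner: Planning, Simulation and
    Vegetation Structure Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A virtual instrument for economical stepper-driven pan-tilt
    terrestrial LiDAR scanners. Translates motor, gearing and timing
    parameters into angular resolutions, scan schedules, durations and
    point counts; tracks laser orientation by dead reckoning over stepper
    motor movements; converts horizontal-coordinate range records into
    Cartesian point clouds with off-axis mount offset correction; simulates
    scans of synthetic forest scenes by ray casting with the rangefinder's
    quantization and accuracy error model; and produces the standard
    vegetation-structure product chain (ground classification, TIN digital
    terrain model, height normalization, canopy height model, tree height
    estimation). Includes point-density diagnostics over the scan sphere,
    tilt-adaptive microstepping plans for uniform density, restricted scan
    windows, and readers/writers for raw scan tables, ASCII XYZ, LAS and
    ESRI ASCII rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
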
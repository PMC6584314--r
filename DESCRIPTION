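Package: permchip
Title: Barrier Permeability Analysis for Radial Microfluidic Organ-on-Chip Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies passive tracer permeability of endothelial barriers in
    radial two-compartment microfluidic chips from fluorescence time-lapse
    image stacks. Provides chip geometry rasterization into region-of-interest
    masks, a forward two-compartment transport simulator that renders noisy
    16-bit acquisitions with ground-truth manifests, per-frame intensity
    extraction with apical-equilibrium gating and normalization, weighted
    linear slope fitting with inflection/plateau window selection, conversion
    of slopes to permeability via the volume-to-surface ratio, series
    subtraction of the acellular scaffold resistance, piecewise temporal and
    azimuthal sector permeabilities, and wall-shear ramp scheduling for flow
    conditioning of endothelial monolayers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
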
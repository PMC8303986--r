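Package: pbsflash
Title: Dose and 3D Dose-Rate Engine for Proton Pencil-Beam-Scanning FLASH
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes voxel-wise dose and dose-rate distributions for proton
    pencil-beam-scanning (PBS) transmission fields delivered at ultra-high
    (FLASH) dose rates. Implements the three dose-rate metrics in current use
    for PBS FLASH research: the dose-averaged dose rate (DADR), the averaged
    dose rate (ADR) with a dose-threshold-trimmed irradiation window, and the
    dose-threshold dose rate (DTDR). Includes a machine calibration model
    linking monitor units, proton flux, nozzle current and spot peak dose
    rate; a minimum-MU-driven spot delivery timing model with raster
    scanning; a Gaussian pencil-beam dose engine on a regular voxel grid;
    and dose- and dose-rate-volume histograms (DVH/DRVH) with summary
    statistics such as V40Gy/s and D2%. Fixture generators reproduce a
    water-phantom benchmark field and a synthetic multi-field cylinder
    phantom, so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    grDevices,
    mgcv,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'machine.R'
    'delivery.R'
    'dose-engine.R'
    'metrics.R'
    'histograms.R'
    'fixtures.R'
    'io.R'
    'show-methods.R'
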
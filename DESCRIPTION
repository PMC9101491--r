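Package: wheatBRF
Title: Organ-Scale Bi-Directional Reflectance Factors of Wheat from
    Nadir Multispectral Images and Incident-Light Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes wheat canopy bi-directional reflectance factor (BRF)
    maps at the organ scale from co-registered nadir multispectral images
    and downwelling irradiance spectra. Provides camera response-curve
    calibration against a multi-target reference panel (DN-intercept
    forced through the origin), per-band digital-number to BRF conversion,
    cloudiness-gated soil/leaf/ear segmentation with a first-local-minimum
    near-infrared threshold, per-organ BRF pooling, panel-based inter-date
    correction with a begin/end consistency rule, NOAA solar-position and
    solar-noon utilities, and a forward scene simulator so the whole chain
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, tiff, png, jsonlite, yaml, pracma
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'solar.R'
    'spectral.R'
    'radiometry.R'
    'brf.R'
    'segmentation.R'
    'correction.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
    'wheatBRF-package.R'
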
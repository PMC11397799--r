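Package: canopyspec
Title: Multispectral Plant Canopy Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for top-view multispectral plant images:
    chlorophyll-fluorescence-driven canopy segmentation, phase-correlation
    registration of a misaligned near-infrared channel, per-pixel spectral
    indices (NDVI, ACI) restricted to the plant mask, projected canopy size,
    false-color and histogram outputs, and quadratic treatment-response
    regression.  Includes a synthetic multispectral scene generator with
    analytic ground truth (mask geometry, band reflectances, injected NIR
    misalignment, dose-response structure) so that every pipeline stage can
    be validated without real image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    optparse,
    png,
    stats,
    grDevices,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
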
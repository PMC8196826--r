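Package: mslinescan
Title: Reflectance Estimation for Multishot Linescan Multispectral Cameras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-formation model and reflectance-estimation toolkit for
    multishot linescan multispectral cameras whose frames are acquired
    sequentially under possibly time-varying illumination. Provides an
    ENVI-style cube reader/writer, a synthetic acquisition simulator with
    known ground truth (scenes, illumination time series, lens attenuation),
    flat-field vignetting correction, six reflectance estimators (full-field
    white reference, white-average, max-spectral, row-wise, double white
    diffuser, and Wiener), spectral correction and negative-value removal,
    reflectance-quality metrics (mean absolute error, spectral angle) with
    an exhaustive ColorChecker patch-split search, and an NDVI vegetation
    segmentation plus supervised crop/weed pixel-classification harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    tools,
    EBImage,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
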
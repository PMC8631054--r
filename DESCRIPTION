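Package: shadowdepth
Title: Depth from Cast-Shadow Offsets: Geometry, Linear and Bayesian
    Observer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how much depth observers infer from the
    offset between an object and its cast shadow.  Implements the
    shadow-projection geometry (offset, illumination slant and tilt,
    penumbra width, pixel/visual-angle conversion), a stimulus renderer
    with disc-kernel penumbra blur and tapered attenuation, a synthetic
    method-of-adjustment observer generator with zero-inflated no-shadow
    controls, the one-parameter generic shadow-to-depth linear model, and
    a Bayesian depth estimator with a beta prior over illumination slant
    and a flat or exponential prior over scene relief.  Fitting functions
    return classed objects with the usual print, summary, coef, predict,
    residuals and plot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
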
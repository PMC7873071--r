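Package: pact3d
Title: Simulation, Calibration and Reconstruction for Hemispherical-Array
    3D Photoacoustic Computed Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for three-dimensional photoacoustic computed tomography
    (3D-PACT) with a rotating hemispherical transducer array: parametrization
    of the four-arc detection geometry and its coaxial scan, an analytic
    N-wave forward model and phantom generators, time-of-flight geometric
    self-calibration of the array (Jacobi iteration over sound speed, point
    source positions and per-element radial factors), universal back-projection
    reconstruction with distance-dependent antialiasing and a two-pass
    dual-speed-of-sound correction (surface extraction, half-ellipsoid fit,
    two-segment straight-ray delays), time-gated motion correction, vascular
    contrast enhancement (depth compensation, denoising, Frangi vesselness,
    blended maximum amplitude projections), and functional time-series
    analysis (bandpass, global signal regression, ROI connectivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    rhdf5,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
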
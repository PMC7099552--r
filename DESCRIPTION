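Package: sinodeform
Title: Sparse-View Tomography via Displacement-Function Sinogram Interpolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates unmeasured projection views in sparse-view parallel-beam
    tomography by per-bin displacement (deformation) functions between adjacent
    measured views, interpolating the displacement field rather than the sinogram
    values. Includes the linear-convolution baselines (view copy, two-view linear,
    band-limited sinc interpolation along the view axis), analytic ellipse-phantom
    simulation, filtered backprojection and Landweber iterative reconstruction with
    a matched Joseph projector/backprojector pair, and sinogram/reconstruction
    error metrics, so sparse-view interpolation methods can be compared end to end
    on synthetic data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
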
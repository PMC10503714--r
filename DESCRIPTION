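Package: svengine
Title: Headless Sedimentation Velocity Analysis with c(s) and ls-g*(s)
    Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automation-compatible engine for sedimentation velocity
    analytical ultracentrifugation (SV-AUC). Implements the
    diffusion-deconvoluted c(s) and the apparent ls-g*(s) sedimentation
    coefficient distribution analyses (finite-element Lamm equation
    kernels, regularized non-negative least squares with systematic
    time- and radial-invariant noise decomposition, and nonlinear
    regression of meniscus, bottom and frictional ratio), driven by a
    command-line/XML control protocol with a handshake flag file so that
    the engine can be spawned headlessly by secondary (e.g. GMP
    workflow) software. Includes a synthetic SV-AUC experiment generator
    for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
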
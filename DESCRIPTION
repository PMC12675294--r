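Package: vascuflow
Title: Diffeomorphic Registration and Generative Modelling of Vascular
    Surfaces via Neural Stationary Velocity Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous deformable registration of a cohort of vascular
    surface point clouds to a common template anatomy.  Surfaces are
    represented as area-weighted point clouds and deformed by the unit-time
    flow of a stationary velocity field parameterized by a fully connected
    neural network, conditioned on trainable per-shape latent codes
    (auto-decoder).  Includes Chamfer-type and debiased Sinkhorn data
    attachment measures, coherent point drift rigid pre-alignment,
    thin-plate spline warping, explicit and implicit flow integrators with
    exact-inverse guarantees, a full training pipeline with adaptive point
    sampling, test-time latent inference, and a generative layer that
    synthesizes new anatomies by sampling and interpolating the learned
    latent space.  Gradients are computed by hand-written reverse-mode
    differentiation, so the package has no deep-learning dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
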
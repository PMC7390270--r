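Package: thrombosim
Title: Thrombin Generation and Venous Clot Growth Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-tier simulator of venous blood coagulation. Implements a
    zero-dimensional platelet-dependent thrombin generation model with assay
    metrics (peak, time to peak, endogenous thrombin potential, lag time), the
    six-species amplification cascade of the propagation phase together with
    its detailed-equilibrium lumping into cubic thrombin kinetics, a reduced
    one-equation bistable reaction-diffusion model of thrombin distribution
    with an analytic wave-propagation criterion and shear-rate threshold, and
    a two-dimensional channel model of clot growth coupling factor transport,
    saturating platelet aggregation, a tissue-factor surface reaction, and
    Stokes-Brinkman hemodynamics with a Davies-law clot permeability.
    Includes packaged, annotated parameter sets and experiment runners for
    platelet-count, shear-rate, and injury-size sweeps.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
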
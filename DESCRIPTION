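Package: stochctrl
Title: Stochastic Control Analysis of Reaction-Network Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes parametric sensitivities (control coefficients) of
    stationary mean levels, noise levels and autocorrelations of continuous-time
    Markov reaction networks under the linear noise approximation, and uses them
    to design parameter perturbations: orthogonal control of noise versus mean,
    generalized minimum-norm multi-target control, tolerance-relaxed control
    metrics, ranking of two-parameter control schemes, iterative noise
    reduction, and amplitude/period control of noisy oscillations. Includes
    exact Gillespie simulation and Euler-Maruyama Langevin integration for
    verification, programmatic model fixtures (birth-death, two-state promoter,
    linear metabolic pathways, negative-feedback oscillator), a structured-text
    model schema, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    compiler,
    deSolve,
    jsonlite,
    MASS,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
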
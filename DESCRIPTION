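Package: dmfsim
Title: Whole-Brain Dynamic Mean-Field Simulation, Inhibitory Calibration
    and Model Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates whole-brain resting-state activity with the
    two-population (excitatory/inhibitory) dynamic mean-field neural mass
    model coupled through a structural connectome, and converts excitatory
    firing rates into BOLD signals with the Balloon-Windkessel hemodynamic
    model using a bounded-memory producer-consumer integrator written in
    C++. Provides feedback inhibition control (FIC) in two forms: a
    closed-form first-order solution giving the inhibitory weight of each
    region as a linear function of global coupling and node strength, and
    the classical iterative calibrator that clamps excitatory rates near
    3.4 Hz. Includes band-pass filtering, functional connectivity (FC),
    sliding-window FC dynamics (FCD) with a pooled Kolmogorov-Smirnov
    objective, joint fitting of global coupling and the excitation-to-
    inhibition ratio by Gaussian-process Bayesian optimization with
    expected improvement, turbulence-like dynamics statistics based on the
    local Kuramoto order parameter, and synthetic connectome/coordinate/
    cohort generators so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
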
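Package: delayosc
Title: Reduction and Synchronization Analysis of Delay-Induced Neural Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for networks of delay-induced oscillators of the
    cortico-thalamic (neural mass) type, in which a single transmission delay
    in a feedback loop destabilizes the rest state and generates limit-cycle
    rhythms. Provides the transcendental linear stability analysis (Hopf
    bifurcation curve of the characteristic equation), a method-of-steps
    Runge-Kutta integrator for constant-delay networks with diffusive
    coupling, center-manifold reduction to coupled Stuart-Landau / complex
    Ginzburg-Landau amplitude equations, numerical phase reduction (direct
    phase response curves and convolution-based phase coupling functions),
    and experiment drivers for critical coupling strength, amplitude death,
    multimodal phase locking, and population-level Kuramoto transitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
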
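Package: vibroseed
Title: Electromagnetic Vibration Seed-Treatment Modelling and Multi-Objective
    Protocol Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A closed-loop modelling toolkit for electromagnetic vibration
    treatment of crop seed. Implements the treatment physics (time-varying
    field, resonance-driven vibration amplitude, absorbed-energy quadrature,
    Helmholtz coil field, electrical power budget), a calibrated virtual seed
    lab (logistic germination kinetics, vigor indices, hormetic dose-response,
    stochastic batch simulation for three maize variety profiles), a hybrid
    GA-PSO cooperative-coevolution multi-objective optimizer with NSGA-II
    machinery and exact hypervolume metrics, a compact CNN-LSTM multi-task
    surrogate trained on self-generated fixtures (synthetic seed images and
    treatment sensor sequences), and command-line entry points tying the
    pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
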
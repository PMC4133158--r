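Package: foragedyn
Title: Temporal and Sequential Dynamics of Free Foraging Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of timestamped multi-option choice logs from free
    foraging experiments. Provides descriptive temporal statistics
    (burstiness and memory coefficients of inter-choice intervals, choice
    entropy, autocorrelogram periodicity), heavy-tail distribution fitting
    (truncated power-law maximum likelihood with Kolmogorov-Smirnov lower
    bound selection, Weibull fits, bootstrap goodness of fit, crossover
    detection for bimodal interval distributions), a dual-state generative
    timing model (power-law bursts alternating with circadian-modulated
    non-homogeneous Poisson gaps) with least-area estimation, run-length
    survival and hazard analysis with Monte-Carlo shuffle tests, and a
    dual-control reinforcement-learning choice model (goal-directed values
    with chosen/unchosen asymmetry plus a habit leaky integrator) with
    maximum-likelihood fitting and BIC/likelihood-ratio model comparison.
    A synthetic-data generator with known ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    fitdistrplus,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
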
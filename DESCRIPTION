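Package: psrfit
Title: Feedback-Control Models of Reflexive Responses to Vocal Pitch
    Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time feedback-control modelling of the pitch-shift
    reflex: a registry of 19 controller configurations from the PID and
    DIVA/state-space families, simulation of normalized fundamental-frequency
    (f_o) trajectories under auditory perturbations, particle-swarm parameter
    fitting, corrected-AIC model comparison with autocorrelation-adjusted
    effective degrees of freedom, cross-validated subject classification with
    intraclass-correlation parameter-stability summaries, and a synthetic
    perturbation-experiment generator emulating sustained-vowel pitch-shift
    study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
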
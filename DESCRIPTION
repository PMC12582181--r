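Package: pritdose
Title: Alpha-Particle Dosimetry and Response Analysis for Pretargeted
    Radioimmunotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biodistribution-driven dosimetry for actinium-225 pretargeted
    radioimmunotherapy (PRIT) in preclinical models. Converts serial ex vivo
    biodistribution data (%IA/g) into time-integrated activities and
    RBE-weighted absorbed-dose coefficients under the local
    alpha-absorption assumption, with mass-dose extrapolation and
    therapeutic indices. Includes Langmuir-type receptor-saturation
    modelling of hapten mass effects, radioligand internalization-kinetics
    summaries, tumor-response classification with native Kaplan-Meier and
    Mantel-Cox log-rank statistics, and a synthetic-data generator that
    emulates the statistical structure of a three-step PRIT animal study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
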
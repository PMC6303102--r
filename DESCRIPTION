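Package: nbtimer
Title: Repressor-Decay and Activator-Relay Timer Models of the Drosophila
    Neuroblast Temporal Transcription Factor Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the temporal transcription factor (TTF) cascade
    (Hunchback, Kruppel, Pdm, Castor) of embryonic Drosophila neuroblasts as
    a four-species ODE circuit, screens random kinetic parameter sets for
    consistency with wild-type and mutant expression sequences, scores each
    consistent circuit for robustness against combinatorial production-rate
    noise, positions circuits in a decay-relay timer space from in-silico
    perturbations (gene deletion, constitutive expression, single-link
    removal), provides closed-form one-step accumulation and decay timers,
    and implements the statistics used to place an in-vivo circuit in the
    same space from staged per-neuroblast staining intensities, together
    with a synthetic staining-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
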
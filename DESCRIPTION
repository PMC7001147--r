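Package: envtacs
Title: Speech-Envelope Transcranial Current Stimulation: Waveforms,
    Adaptive Psychophysics and Multiperiodic Phase Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studies that modulate speech-in-noise comprehension
    with transcranial current stimulation shaped as the phase- and
    latency-shifted speech envelope. Builds stimulation currents from
    speech-like envelopes via the analytic-signal phase shift, runs the
    weighted up-down adaptive staircase for sentence-reception thresholds
    against simulated listeners, and analyses threshold-versus-phase
    profiles with weighted circular tests (Moore-Rayleigh), a discrete
    cosine transform multiperiodic model, LASSO/LARS selection with
    covariance-test inference, and a linear-response nonlinearity
    classifier. Includes a synthetic-data generator with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
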
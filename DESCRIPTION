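Package: cvsleep
Title: Cardiovascular Autonomic Control Model Across Sleep Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delay-differential model of the human cardiovascular system with
    baroreflex autonomic control modulated by higher nervous centres, able to
    simulate the awake state, REM sleep and stage-4 non-REM sleep. An
    integrate-and-fire sinoatrial node drives a pulsatile arterial pressure
    (systolic upstroke plus Windkessel diastolic decay); carotid and lower-body
    baroreceptors feed delayed sympathetic and parasympathetic loops with
    sigmoidal nonlinearities and noradrenaline kinetics. The package also
    provides the companion heart-rate-variability toolkit: interbeat-interval
    extraction and resampling, Welch LF/HF band powers, zero-phase band-pass
    filtering, and the Rosenstein largest-Lyapunov-exponent estimator, plus an
    ensemble experiment driver that regenerates the model's spectral and
    statistical indices per sleep stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
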
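Package: swasim
Title: Simulation and Estimation of Sleep Homeostasis (Process S) from
    Mouse EEG Slow-Wave Activity
Version: 0.1.0
Authors@R:
    person("swasim", "maintainers", email = "swasim@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the homeostatic regulation of sleep in
    mice at 4-second epoch resolution. Implements an elaborated
    two-process model in which EEG slow-wave activity (SWA, 0.5-4 Hz
    power) tracks a homeostatic Process S through coupled differential
    equations driven by binary wake and REM-sleep trigger functions
    derived from a scored hypnogram. Provides hypnogram and SWA data
    structures with TSV input/output, spectral band-power computation,
    NREM-sleep episode and long-wake-bout detection, a fast fixed-step
    integrator for the model equations, a light/dark-balanced squared
    error objective, a two-stage multi-start Nelder-Mead estimator for
    the Process S parameters (gain constant, rise rate, upper
    asymptote), and a seeded semi-Markov generator of synthetic mouse
    sleep architecture with model-generated noisy SWA for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
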
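Package: bioicd
Title: Frequency-Sensing Anti-Arrhythmic Ion Channel Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates a biologically integrated cardiac defibrillator: an
    engineered ion channel whose Markov gating senses the cardiac activation
    frequency and injects a depolarizing current only during tachyarrhythmia,
    terminating reentry so that sinus rhythm resumes. Couples the channel to
    the epicardial ten Tusscher-Panfilov 2006 human ventricular myocyte model,
    provides a 2D monodomain finite-difference tissue solver with pathological
    substrates (functional reentry, spiral-wave breakup, diffuse fibrosis,
    scar with grey zone), S1-S2 cross-field arrhythmia induction, an in-silico
    dynamic-clamp pacing protocol with refractory-beat feedback, and metrics
    quantifying arrhythmia detection and termination timing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
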
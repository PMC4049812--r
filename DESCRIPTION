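Package: asppr
Title: Advance Seizure Prediction from Intracranial EEG via Pre-Ictal
    Relabeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific advance prediction of epileptic seizures from
    multi-channel intracranial EEG. Converts 6-channel 256 Hz recordings into
    a 204-feature instance stream (signal and accumulated energy, Daubechies
    wavelet sub-band energies, spectral band power and spectral edge
    frequency, statistical moments, largest Lyapunov exponent and correlation
    dimension), labels instances into the four peri-ictal states, relabels
    data to target seizure onset N to N+5 minutes ahead, selects features by
    multi-class ReliefF, trains class-weighted one-against-one radial-basis
    support vector machines with grid-searched hyperparameters, and evaluates
    predictions with prediction-conditioned Sensitivity, Specificity and
    their harmonic mean (S1) against analytic baseline and random predictors.
    Includes a deterministic synthetic EEG generator so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
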
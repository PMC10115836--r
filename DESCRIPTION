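Package: delaysync
Title: Visuomotor Delay Identification and Heterogeneous-Delay Swarm Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying visuomotor transport delays of flying
    insects tracking a moving stimulus, and for analysing how a population of
    such delays shapes the stability of a visually interconnected swarm.
    Provides a synthetic-data generator (triangular stimulus schedules,
    linear responder models with transport delays, shifted-gamma delay
    populations, multi-camera pixel detections), multi-camera 3-D tracking
    (data association by reprojection error, DLT triangulation, Kalman
    bridging of dropouts, coherence-based solo/group segmentation),
    frequency-domain system identification (Welch coherence, chirp
    Z-transform spectra, rational transfer-function fits over a transport
    delay grid) and time-domain ARX identification for short records,
    shifted-gamma delay-distribution fitting, delay differential equation
    simulation of an attraction-repulsion swarm and its mean-field
    reduction, and Hopf stability boundaries for gamma-distributed delays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
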
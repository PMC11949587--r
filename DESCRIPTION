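Package: hopfconn
Title: Hopf Whole-Brain Modelling of Phase-Lag-Index Functional Connectivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates networks of Hopf (Stuart-Landau) oscillators on a
    weighted structural connectome, computes phase-lag-index (PLI) functional
    connectivity from band-limited signals, fits the model to empirical PLI by
    two-dimensional grid search over the global coupling strength and the
    excitability (Hopf bifurcation) parameter, quantifies the normalized
    coupling strength k = K/sqrt(lambda), and performs functional connectotomy:
    masking tumor regions out of the fitting objective and measuring the
    induced change in optimal coupling against a paired control. Includes a
    seeded synthetic-cohort generator producing connectomes, alpha-band
    natural-frequency profiles, ground-truth "empirical" PLI matrices, and
    two-cohort designs with tumor-localized coupling inflation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
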
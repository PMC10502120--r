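Package: phaseflow
Title: Growth Phase Inference for Bacterial Populations in Flow-Through
    Ecosystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the in situ growth phase (acceleration, mid-log,
    deceleration, stationary) of abundant bacterial populations sampled
    longitudinally from metagenomes, such as dense human stool time
    series.  Provides closed-form logistic growth analytics with
    second-derivative phase-boundary geometry, a stochastic logistic
    growth (Euler-Maruyama) ensemble simulator with noise on abundance
    or on carrying capacity and an optional harvest (dilution) term,
    longitudinal statistics on centered log-ratio abundances and log2
    peak-to-trough replication rates (delta computation,
    regression-to-the-mean diagnostics, per-taxon regressions with
    Benjamini-Hochberg correction, Fisher's method, augmented
    Dickey-Fuller stationarity screening), a rule-based growth-phase
    classifier, and a synthetic donor generator with known ground-truth
    phases for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    vegan
Config/testthat/edition: 3
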
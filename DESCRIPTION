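Package: gaitagree
Title: Dual-Modality Treadmill Gait Analysis and Method Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes spatiotemporal and stability gait parameters from two
    independent measurement modalities recorded on a treadmill - a depth-camera
    skeleton stream (30 Hz joint positions) and a network of six inertial
    measurement units (128 Hz) - and quantifies their agreement. Includes
    coordinate-based and gyroscope-based detection of initial contact and
    toe-off, stride length by ankle displacement plus belt translation and by
    double integration of foot acceleration, single and double support times,
    step width, arm swing amplitude, and the margin of stability from an
    extrapolated centre-of-mass inverted pendulum model. Method agreement is
    assessed with paired tests, convergent-validity correlations and
    Bland-Altman limits of agreement. A synthetic treadmill-gait generator
    with analytic ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
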
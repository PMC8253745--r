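Package: vestigait
Title: Vestibulo-Motor Coupling and Dynamic Stability Analysis for Walking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify how stochastic electrical vestibular
    stimulation (EVS) couples to muscle activity and ground reaction forces
    across walking conditions. Provides a band-limited stochastic stimulus
    generator, a multirate synthetic walking-trial simulator with known
    injected vestibulo-motor coupling, heel-strike detection from force-plate
    and centre-of-pressure signals, stride-synchronized signal conditioning,
    Morlet-wavelet time-frequency coherence and gain over the gait cycle with
    the analytic per-point significance bound, local dynamic stability via
    Rosenstein's local divergence exponent, and condition comparisons by
    cluster-based permutation tests and repeated-measures ANOVA with planned
    pairwise contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
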
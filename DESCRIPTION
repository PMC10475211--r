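Package: scnkuramoto
Title: Coupling Strength Inference in the Suprachiasmatic Nucleus with Noisy
    Kuramoto Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse circadian phase coherence of single-cell
    PER2::LUC bioluminescence rhythms in the suprachiasmatic nucleus (SCN)
    and to infer neuronal coupling strength with noisy mean-field Kuramoto
    models.  Provides stochastic simulation of one- and two-community phase
    oscillator networks rendered as realistic bioluminescence traces, peak
    detection and inclusion filtering, Kuramoto order parameters, random
    matrix theory based community detection, interval estimation of coupling
    and noise strength from phase-increment moments and Bessel-ratio
    self-consistency, per-condition linear coupling relations for two
    interacting communities, and a constrained search-space analysis of
    adaptive capacity across age and photoperiod conditions.
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
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
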
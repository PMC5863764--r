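Package: naptools
Title: Sleep EEG Analysis of Targeted Memory Reactivation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for targeted memory reactivation (TMR)
    experiments in NREM sleep: cue-locked epoching with two-step artifact
    rejection, event-related potentials and Hanning-taper time-frequency
    power, discrete sleep-spindle and slow-oscillation detection,
    SO-spindle phase coupling with circular statistics, sliding-window
    spatiotemporal representational similarity analysis, cluster-based
    permutation inference, and behavioral retention scoring. Includes a
    synthetic polysomnography generator with full ground truth so every
    stage is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
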
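Package: odortask
Title: Discrete-Event Simulation and Analysis of Automated Olfactory
    Training Protocols for Head-Fixed Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software-only engine for the automated training protocols used
    with head-fixed mice in olfactory tasks: delayed non-match to sample
    (DNMS), delayed paired association (DPA), go/no-go (GNG) and GNG
    reversal. Implements the three training phases (lick teaching, shaping,
    full task) as discrete-event state machines driven by simulated mouse
    agents, a first-order kinetic model of olfactometer odor delivery, and
    the standard behavioral analysis toolkit (blocked performance, hit and
    false-choice rates, d-prime with extreme-rate clipping, licking
    efficiency, smoothed lick-rate curves, trials to criterion). Session
    logs round-trip through plain-text event files, and a small command-line
    interface mirrors the daily simulate/analyze workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
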
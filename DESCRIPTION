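Package: homecage
Title: Home-Cage Operant Phenotyping: Contingency Replay, Behavioral
    Scoring and Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated home-cage operant phenotyping of
    group-housed mice in IntelliCage-style apparatus. Implements the
    Habituation/Alternation/Reversal reinforcement-contingency state
    machine (deterministic replay of corner-visit and nosepoke streams,
    side reversals, non-licker fallback), the standard behavioral
    measures (corner-entry and lick rates by light phase, repeat-visit
    percentage, windowed percent alternation, collected-reward
    efficiency), trajectory-based activity endpoints (per-mouse
    locomotion, immobility below a speed cutoff, rearing/climbing), an
    agent-based simulator of circadian-modulated cohorts with
    genotype-effect presets, and permutation-based group comparison with
    simulation-based power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
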
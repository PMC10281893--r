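Package: breath4dct
Title: Breathing-Signal Irregularity Analysis and Desk-Scale 4D CT
    Acquisition Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying breathing irregularity from respiratory
    surrogate signals (amplitude variability of individual breathing cycles
    and breathing pauses), for selecting and matching irregular-breather
    cohorts by those statistics, and for simulating -- on the signal level --
    the two clinically used 4D CT acquisition strategies: conventional
    retrospectively gated spiral scanning and breathing-adapted sequence
    scanning that keeps the beam on at each couch position until a
    representative breathing cycle has been captured.  A seeded synthetic
    breathing-signal generator with ground-truth cycle and pause annotations
    makes every analysis stage testable without clinical data.  Includes
    self-contained Mann-Whitney U and Spearman rank statistics used in the
    cohort comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
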
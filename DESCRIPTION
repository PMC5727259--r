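Package: chancoupler
Title: Stoichiometry and Coupled-Gating Analysis for Voltage-Gated Sodium
    Channel Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to test whether voltage-gated sodium channel alpha-subunits
    assemble and gate as dimers. Implements binomial dominant-negative
    dose-response fitting (y = (1-x)^n for candidate stoichiometries),
    photobleaching step counting with maturation-corrected subunit-count
    inference, segment-based idealization of single-channel records with
    classification of openings as coupled or uncoupled, Boltzmann and
    biexponential gating-curve fits with an independent-channels mixture
    null, and FRET crosstalk correction. A synthetic-data module simulates
    two-protomer Markov gating with a tunable coupling fraction,
    photobleaching trace populations, dominant-negative suppression curves
    and Boltzmann gating data so every analysis stage is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
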
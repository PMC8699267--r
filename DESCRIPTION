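Package: ms1transfer
Title: MS1-Level Transfer of Peptide Identifications Between LC-MS Runs
    with Target-Decoy Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Match-between-runs transfer of MS1 peptide/protein
    identifications from immunodepleted plasma runs, organised as a
    four-layer database by depletion depth, to undepleted runs.
    Implements retention-time alignment with anchor-based warping,
    cross-run consensus feature linking within ppm and retention-time
    tolerances, label-free protein rollup, two target-decoy
    false-discovery-rate procedures for transferred identifications
    (dilution-linearity R-squared scoring with column-shuffled decoys,
    and an empirical plasma-probability score with simulated decoys),
    quantitative quality-control statistics (lognormal coefficient of
    variation, dilution-median linearity, abundance deciles), and
    synthetic LC-MS feature generators with known ground truth for
    dilution series, depletion ladders and plasma cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
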
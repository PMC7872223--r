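Package: mempart
Title: Membrane Partitioning and Translocation Free-Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for one-dimensional membrane permeation free
    energetics of small amphiphiles such as quorum-sensing modulators.
    Generates biased umbrella-sampling data on model free-energy landscapes,
    reconstructs potentials of mean force with the weighted histogram
    analysis method (WHAM) including a two-block error protocol, extracts
    partition (dG_par) and translocation (dG_trans) free energies with a
    plateau linear-extrapolation rule for sliced partition-coefficient
    profiles, converts between PMFs and water-membrane partition
    coefficients, and associates partitioning free energies with screening
    descriptors and EC50/IC50 potency measurements.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
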
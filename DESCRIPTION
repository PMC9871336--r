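Package: kinrace
Title: Kinetic-Race Analysis of Kinesin Processivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts single-molecule motility observables for kinesin motors
    (run lengths, microtubule dwell times, stopped-flow observed rates,
    pelleting affinities) into chemomechanical cycle rate constants through
    the kinetic-race model of processivity, in which each stepping cycle is a
    race between tethered-head attachment and detachment of the bound head.
    Provides uncertainty-propagating rate arithmetic, censored
    single/double-exponential maximum-likelihood fitting, Michaelis-Menten and
    Langmuir isotherm estimation, a seeded Monte-Carlo simulator of the
    stepping cycle with pixel/frame detection censoring, and peptide
    net-charge and Debye-length electrostatics for charge-processivity
    regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
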
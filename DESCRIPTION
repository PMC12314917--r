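Package: thylakem
Title: Photoelectrochemical Analysis of Thylakoid-Membrane Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing photoelectrochemical measurements of
    photosynthetic membranes wired to electrodes. Parameterises chopped-light
    chronoamperometry traces into Spike Charge and Steady State Photocurrent,
    assigns interfacial electron-transfer pathways from stepped
    chronoamperometry (onset, maximum and decay potentials), estimates
    midpoint potentials from cyclic voltammetry, and fits P700
    oxidation/re-reduction kinetics from co-recorded spectrophotometer
    traces. Includes a deterministic kinetic simulator of the coupled
    photosynthetic and respiratory electron-transport chains of a
    cyanobacterial thylakoid membrane exchanging electrons with an electrode
    through potential-gated pathways, used to generate synthetic data with
    the structure the analysis assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
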
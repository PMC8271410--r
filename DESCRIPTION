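Package: pbdesynergy
Title: Queuing-Score Evaluation and Design of Plant-Microbe Synergistic
    Degradation of Polybrominated Diphenyl Ethers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating and improving the synergistic degradation
    of polybrominated diphenyl ethers (PBDEs) by plants and soil
    microorganisms. Converts per-enzyme molecular docking scores into
    rank-based single scores and a weighted composite synergy score;
    builds CoMFA-style 3D-QSAR models (steric and electrostatic lattice
    fields, NIPALS partial least squares with leave-one-out
    cross-validation and external validation); screens designed PBDE
    derivatives by relative change in predicted degradability, flame
    retardancy (C-Br bond dissociation enthalpy) and environmental
    endpoints (EC50, log BCF, vapor pressure); screens soil regulatory
    factors with Taguchi L12 and full-factorial designs using
    signal-to-noise ratios; and summarizes protein-ligand contact tables
    and MM/PBSA energy ledgers. Ships the worked score, prediction,
    response and interaction tables as plain-text fixtures together with
    seeded synthetic-data generators so the whole pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
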
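Package: navgate
Title: Markov Voltage-Clamp Simulation and Analysis of Nav-Channel Fast
    Inactivation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying fast inactivation in voltage-gated sodium
    (Nav) channels as a multi-step gating process with a conductive
    ("leaky") inactivated state. Provides a labelled-state Markov
    voltage-clamp simulator with Goldman-Hodgkin-Katz (GHK) multi-ion
    currents and gating currents, a synthetic cut-open-oocyte recording
    generator (capacitive transients, band-limited noise, P/N leak
    subtraction), an electrophysiology analysis pipeline (exponential
    kinetics, gating-charge immobilization, Boltzmann G-V/Q-V/h-infinity
    fits, time-resolved GHK selectivity from instantaneous I-V curves),
    and a HOLE-style pore-radius profiler that detects the two-tier
    hydrophobic constriction at the intracellular end of S6 and maps the
    lining residues across isoforms by pairwise sequence alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    tools,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
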
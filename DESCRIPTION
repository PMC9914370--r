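Package: ovtsim
Title: Tumor-Immune Dynamics of Oncolytic Virotherapy with Anti-CTLA-4 Blockade
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a nine-compartment ordinary differential equation model
    of murine melanoma under combined oncolytic virotherapy (OV) and anti-CTLA-4
    immune checkpoint blockade. Provides stiff integration of the tumor-immune
    system (susceptible and infected tumor cells, free virions, CD8+ and CD4+
    T cells, IFN-gamma, CTLA-4 molecules, anti-viral immune cells and natural
    killer cells) under time-windowed treatment schedules, the tumor-free
    equilibrium and its stability conditions, named validation scenarios and
    dose/blockade sweeps with bisection search for eradication thresholds, and
    global sensitivity analysis by Latin hypercube sampling with partial rank
    correlation coefficients against a dummy-parameter significance floor.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    lhs,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
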
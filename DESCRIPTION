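Package: masSidebands
Title: Spinning-Sideband Simulation and CSA Analysis for Partially
    Oriented Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting slow magic-angle-spinning (MAS)
    carbon-13 NMR spectra of partially oriented biomolecular samples
    such as strained collagen fibres.  Converts quantum-chemical
    shielding tensors to chemical-shift tensors in the Haeberlen and
    IUPAC conventions, generates molecular orientation distributions by
    uniform-area sampling on a prolate ellipsoid projected onto the unit
    sphere, simulates MAS spinning-sideband intensity patterns for
    chemical-shift-anisotropy (CSA) bearing spins by exact
    rotor-phase-averaged Fourier analysis, builds composite
    Gly/Pro/Hyp collagen carbonyl patterns, runs strain and alignment
    sweeps of sideband intensity ratios, and fits Haeberlen CSA
    parameters to sideband patterns or rendered spectra by multi-start
    least squares.  A synthetic-data generator emulating per-strain
    tensor tables and noisy slow-MAS spectra makes the whole pipeline
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
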
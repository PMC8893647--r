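Package: cngrowth
Title: Coarse-Grained Eukaryotic Cell Growth and Nuclear Size Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates coarse-grained eukaryotic cell growth from the kinetics
    of amino-acid import, non-ribosomal and ribosomal protein synthesis,
    ribosome assembly in the nucleus, active nucleocytoplasmic transport, and
    protein degradation / ribosome disassembly. Cytoplasmic and nuclear
    volumes are derived from macromolecule counts, so the model predicts the
    cell-to-nucleus volume (C/N) ratio alongside the growth rate. Includes
    the parameter-calibration arithmetic that derives the default yeast rate
    coefficients from physiological constraints, deterministic single-lineage
    simulation with division at volume doubling, parameter scans and
    normalized sensitivity gradients, and a stochastic population simulator
    with a volume-dependent division hazard and optional two-protein
    regulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
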
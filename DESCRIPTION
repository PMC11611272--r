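Package: mitofission
Title: Mass-Action Dynamics and Global Sensitivity Analysis of
    Drp1/Mff-Dependent Mitochondrial Fission
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic mass-action model of Drp1-dependent mitochondrial
    fission in which cytosolic Drp1 tetramers bind the outer-membrane receptor
    Mff and the resulting complexes assemble, one unit at a time, into
    oligomers that trigger fission once they exceed a size threshold. The
    package integrates the 32-state dimensional system and its
    nondimensionalized counterpart with a compiled stiff solver, computes the
    total fission rate (TFR) and cumulative total fission, locates fixed
    points by damped Newton iteration and classifies their stability from the
    Jacobian eigenvalue spectrum (including the Hopf bifurcation in the
    build-to-disassembly ratio mu), and quantifies parameter influence with
    one-at-a-time scans and a native Saltelli/Sobol variance-based
    sensitivity engine with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
NeedsCompilation: yes
Config/testthat/edition: 3
RoxygenNote: 7.3.3
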
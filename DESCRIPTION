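Package: HetPattern
Title: Stochastic Simulation of Heterocyst Patterning on Growing
    Cyanobacterial Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates heterocyst differentiation along growing filaments
    of Anabaena-like cyanobacteria. A gene-regulatory network (HetR, PatA,
    PatS/PatX, HetN, the mobile ERGSGR hexapeptide inhibitor and fixed
    nitrogen) is integrated per cell with Langevin (Ito) chemical kinetics
    on a one-dimensional lattice whose cells grow and divide. Terminal
    cells leak inhibitor and fixed nitrogen to the medium, which is enough
    to produce terminal heterocysts in the patA mutant. The package
    provides mutant overlays, pattern statistics (vegetative intervals,
    heterocyst percentage, cluster sizes, terminal heterocysts), a
    Kolmogorov-Smirnov-based energy function with simulated-annealing
    calibration, a relative sensitivity analysis, and a continuum
    reaction-diffusion toy model demonstrating how absorbing boundaries
    create activator maxima at filament ends.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
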
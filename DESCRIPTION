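Package: confinedwater
Title: Analysis of Confined Water Dynamics in Molecular Simulation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the dynamics of water confined in narrow
    protein pores from molecular simulation trajectories: slab residence-time
    profiles and axial densities, retention (survival) curves and exchange
    kinetics around a reference site, dipole and H-H orientation statistics,
    geometric hydrogen-bond detection, radial distribution functions,
    group-group Coulomb and Lennard-Jones interaction energies, and a
    harmonic-oscillator model of the rock, twist and wag librational modes of
    rigid three-site water, including a driven-damped-rotor demonstrator of
    frequency-selective terahertz field coupling. Includes seed-reproducible
    synthetic trajectory generators (compartment jump process, Brownian walk,
    orientation fields, librational oscillation) with recorded ground truth,
    plus readers and writers for multi-model PDB, multi-frame GRO and
    extended-XYZ trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    deSolve,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
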
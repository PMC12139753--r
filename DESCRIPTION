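Package: fclsim
Title: Particle-Based Simulation of Flat Clathrin Lattice Dynamics
Version: 0.1.0
Authors@R:
    person("FCL", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Coarse-grained, particle-based reaction-diffusion simulation of
    flat clathrin lattice (FCL) assembly and disassembly on a membrane patch.
    Rigid triskelion clathrin particles bind reversibly to membrane-resident
    AP-2 adaptors and to each other, diffuse by Brownian dynamics, and form
    planar hexagonal lattices. The package provides the simulation engine,
    cluster-dynamics statistics (equilibration time, modal cluster-number
    pattern, mean cluster size, dwelling time, neighbor densities), parameter
    sweep and growth-factor stimulus protocols, synthetic-data generators with
    analytic ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
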
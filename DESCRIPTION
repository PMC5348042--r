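Package: axskel
Title: Coarse-Grained Molecular Dynamics of the Axon Membrane Skeleton
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained bead-spring model of the periodic axon plasma
    membrane skeleton: circumferential actin rings connected by spectrin
    tetramers anchored to the lipid bilayer through ankyrin/Nav particles.
    Provides deterministic builders for the skeleton geometry, the full
    force field (harmonic bonds, shifted repulsive Lennard-Jones sterics,
    FENE ring-bending and inter-ring restraints, breakable actin-spectrin
    association, bilayer confinement, and an expanding cylindrical wall),
    NVT dynamics with a Beeman integrator and Berendsen thermostat, and
    scripted in-silico experiments: radial-expansion stiffness with
    thin-shell inversion to Young's moduli, ankyrin thermal-motion
    statistics, spectrin laceration/reconnection, and persistence-length
    estimation for free chains. Also fits AFM force-indentation curves to
    closed-form power laws for thin-walled cylinder and cuboid geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
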
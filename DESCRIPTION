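Package: trapflow
Title: 3D Incorporation Dynamics of Nanoparticles in a Tightly Focused
    Optical Trap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the three-dimensional
    incorporation of dielectric nanoparticles into an optical trap imaged
    by multiplane widefield microscopy. Computes the tightly focused
    vectorial field of the trapping beam by the angular spectrum
    (Debye-Wolf) representation, derives a dipole-approximation optical
    force field, propagates optically driven Brownian nanoparticles with
    optional pairwise Oseen hydrodynamic coupling, renders and tracks the
    particles in synthetic eight-plane widefield image stacks using phasor
    localization, and reconstructs concentration, velocity, force, Peclet,
    trap-energy and flux fields together with incorporation-channel fits
    and power-law scaling analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'camera.R'
    'medium.R'
    'trajectory-set.R'
    'field-maps.R'
    'channels.R'
    'constants.R'
    'optical-train.R'
    'focal-field.R'
    'force-field.R'
    'dynamics.R'
    'io.R'
    'localize.R'
    'traj-analysis.R'
    'pipeline.R'
    'trapflow-package.R'
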
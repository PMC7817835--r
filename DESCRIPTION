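Package: ODAcurate
Title: Coordinate-Level Curation of Axial Dynein Particle Lattices on Microtubule Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for curating single-particle cryo-EM coordinate metadata of
    filaments decorated with periodically bound complexes, such as outer dynein
    arms (ODAs) on doublet microtubules. Picked filaments are segmented into
    8-nm particles at an 82 Angstrom step, particles classified into the three
    lattice registers of the 24-nm repeat are unified onto a single reference
    phase, missing neighbors are recovered at +/-1 and +/-2 repeats along the
    filament axis and verified iteratively, duplicates are removed, and axial
    periodicity and cluster statistics are reported. Includes a synthetic
    splayed-axoneme coordinate simulator with ground truth for validating the
    full pipeline, and lossless STAR/CSV particle-table interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'star.R'
    'coords-io.R'
    'filament-geometry.R'
    'register-curation.R'
    'neighbor-recovery.R'
    'periodicity-qc.R'
    'synthetic-data.R'
    'pipeline.R'
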
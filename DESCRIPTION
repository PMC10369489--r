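Package: dimergrow
Title: Growth-Mode Analysis of Protein Dimer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deciding whether a protein dimer interface can
    propagate into an amyloid-like polymer. The dimer interface is reduced
    to two angles, a polymerization angle and a polymerization dihedral,
    computed from solvent-accessibility-derived interface residues and
    geometric centers. An idealized two-sphere model propagates each
    (angle, dihedral) pair into a chain of tangent spheres and classifies
    growth as limited (the chain collides with itself) or unlimited, with
    subtypes head-to-head, doughnut, helical and linear. A grid scan over
    both angles yields a growth landscape with a fitted limited/unlimited
    boundary, and an atomic replication protocol propagates real dimer
    structures into polymer chains with steric-clash counting. Includes
    gyration-tensor shape descriptors (asphericity, sphericity), rigid
    superposition with screw-axis decomposition, and a synthetic-structure
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
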
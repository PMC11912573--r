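Package: pentatube
Title: Geometry of Pentamer-Based Protein Cages and Nanotubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@pentatube.org",
           role = c("aut", "cre"))
Description: A geometric toolkit for pentamer-based protein cage and nanotube
    polymorphism. Measures bending and torsion angles between polygon-shaped
    capsomers ("AngelaR"), in synthetic assemblies or atomic models read from
    PDB files. Implements a pentagon planar-lattice model of straight tubes
    with helicity/periodicity enumeration, edge-contact-percentage scoring and
    flip screening, an iterative bending/torsion helix builder for twisted
    tubes with thread-gap metrics, and capsomer interaction-network rewiring
    that enumerates alternative tube architectures. Includes parameterized
    synthetic assembly generators (dodecahedral cages, spherical cage shells,
    straight and twisted tubes, noisy variants) so every analysis is testable
    without structural databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
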
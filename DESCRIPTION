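Package: nanoroll
Title: Digital Construction, Relaxation and Atomistic Description of
    Single-Layer-Material Nanotubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds nanotubes by rolling two-dimensional single-layer
    materials (graphene, graphane, graphynes, silicene, germanene,
    hexagonal boron nitride, bilayer silicas, MoS2 and WS2) along a
    rolling vector defined by integer chiral indices, with full support
    for non-zero-thickness layers and negative indices.  Finds the
    translational primitive cell of a tube by exact lattice algebra with
    a seam-mismatch search fallback, relaxes sheets and tubes with an
    embedded Stillinger-Weber force field for transition-metal
    dichalcogenide monolayers using a FIRE minimizer, and computes a
    thirty-descriptor atomistic feature table (energies, coordination,
    common-neighborhood parameter, radii, perimeters, thicknesses)
    suitable as machine-learning input for nanosafety modelling.
    Structures are exchanged as extended-XYZ and LAMMPS data files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
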
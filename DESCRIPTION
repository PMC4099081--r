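Package: dcpve
Title: Poro-Viscoelastic Modelling of an Idealised Decompressive Craniectomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling soft-tissue herniation through a circular
    opening in a rigid boundary, an idealised decompressive craniectomy.
    Provides closed-form poro-viscoelastic (PVE) constitutive functions
    (Prony-series stress relaxation with ramp correction, Terzaghi
    consolidation), nonlinear least-squares identification of PVE parameters
    from unconfined and confined compression relaxation curves, an
    axisymmetric mixed displacement-pressure finite-element solver for Biot
    consolidation with Prony solid relaxation, marker-based planar strain
    extraction from image stacks (detection, trajectory linking, polynomial
    smoothing, Delaunay triangulation, constant-strain-triangle fields), and
    seeded synthetic-data generators for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    deldir,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    optparse
Config/testthat/edition: 3
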
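Package: craniofem
Title: Cranio-Mandibular Finite-Element Biomechanics of Saber-Toothed Biting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A comparative cranio-mandibular biomechanics pipeline for
    muscle-driven biting simulations. Provides a small linear-elastic
    finite-element engine (four-noded tetrahedral solids, pretensioned truss
    musculature, beams, rigid links), a parametric synthetic skull generator
    with labelled canine dentine/enamel regions and articular joint geometry,
    a temporomandibular-joint hinge and a three-dimensional maximum-gape
    estimation algorithm based on articular cartilage offsetting and
    iterative-closest-point seating, canine arc-centre geometry, dry-skull
    muscle force estimation, and allometric two-thirds-power bite-force
    scaling with muscle-recruitment back-calculation and regional or
    landmark-based von Mises stress summaries for cross-model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
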
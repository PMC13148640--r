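Package: paleolimb
Title: Musculoskeletal Modelling and Stance Inference for Extinct Archosaurs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline pipeline for inferring locomotor function in extinct
    archosaurs from digital skeletal models. Estimates body segment
    parameters (mass, centre of mass, inertia) from watertight triangle
    meshes with zero-density air cavities, builds joint coordinate systems
    from geometric primitives fitted to articular surfaces, scans joint
    ranges of motion with collision and disarticulation tests, computes
    muscle moment arms by tendon excursion over paths with via points and
    cylinder/sphere wrapping surfaces, reconstructs muscles by
    maximum-parsimony character optimisation under the Extant Phylogenetic
    Bracket, and classifies quadrupedal versus bipedal stance with
    allometric mass estimation and repeated linear discriminant analyses.
    Includes a synthetic-data generator producing fixtures with closed-form
    or exhaustively enumerated reference answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    minpack.lm,
    ape,
    grDevices,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
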
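Package: plateforge
Title: Parametric Contact-Surface Modelling of Distal Humerus Fixation Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-adaptable extra-articular distal humerus plate
    models from a bone surface mesh. Extracts the anatomical axis and
    anterior-posterior frame of a long bone, slices cross-sections, reads
    Left/Middle/Right region-of-interest points from each section, fits
    circular arcs through them and assembles a compact parametric plate
    description (arc angles, centre-to-axis distances, supporting distances,
    thickness). The parameter set drives a lofted contact surface, an
    alternative Catmull-Clark subdivision surface fitted to the bone, a
    thickened watertight plate solid ready for 3D printing, signed
    deviation analysis between plate and bone, and free-form-deformation /
    projection-scaling personalization. Includes a seeded synthetic humerus
    generator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
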
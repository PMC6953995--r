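Package: morphable3d
Title: Large-Scale 3D Morphable Models of Anatomical Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical shape and texture models ("morphable models")
    of anatomical surfaces, such as human faces, from collections of raw
    triangle meshes. Provides automatic 3D landmarking by rendered-view
    back-projection, landmark-guided non-rigid iterative closest point (NICP)
    dense correspondence against a template, generalized Procrustes alignment,
    PCA shape and texture models with demographic sub-models, automatic
    chi-square pruning of registration failures, and the standard intrinsic
    and fitting evaluation metrics (compactness, generalization, specificity,
    cumulative error distributions). Includes a fully synthetic face-like
    fixture generator with known ground truth so the entire pipeline can be
    exercised and validated without any private scan data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    vegan,
    optparse,
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
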
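Package: rebiom
Title: Reverse-Biomimetic Reconstruction and Simulation of Skeletal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reverse-engineering toolkit for skeletal shape analysis: point-cloud
    cleaning and merging, triangle-mesh input/output (PLY, STL, OBJ, XYZ), mass
    properties and deviation maps, per-vertex principal-curvature estimation with
    mean-Gaussian (HK) and shape-index/curvedness (SC) surface classification,
    curvature-driven region segmentation (tooth cusps, long-bone features),
    referential geometric entities (centroid, principal axes and planes), landmark
    registration, joint centre-of-rotation fitting, B-spline curve and surface
    fitting with fairing, and a 27-bone torque-driven articulated hand model scored
    with Kapandji and Fugl-Meyer pose batteries. Includes parametric synthetic
    generators (long bones, occlusal surfaces, a full hand skeleton, a scanner
    emulator) with known ground truth for parameter-recovery validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, splines, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
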
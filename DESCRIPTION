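Package: bovimetry
Title: Cattle Body-Size Measurement from Segmented 3D Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-contact livestock morphometry from 3D point clouds
    of standing cattle. Implements dynamic unbalanced octree grouping (DUOS),
    a capacity-constrained octree sampling operator with density-filtered
    representative selection, inside a hierarchical PointNet++-style part
    segmentation network trainable at toy scale on CPU, and a segmented-part
    geometric pipeline that measures six body-size parameters (withers height,
    hip height, body length, thoracic, abdominal and cannon circumference)
    via transverse slicing, alpha-shape contour extraction, symmetry-based
    occlusion repair and density-guided keypoint clustering. Includes a
    parametric synthetic-cow generator with analytic ground truth, PLY/PCD
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
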
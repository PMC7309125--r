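Package: facemark3d
Title: Automatic Image-Based Landmarking of 3D Facial Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fully automatic identification of twelve anatomical landmarks on
    triangulated 3D facial surface scans with per-vertex color. Virtual pinhole
    cameras render the mesh, a pluggable 2D face detector and 68-point
    landmarker locate the face in the renderings, and the 2D landmarks are
    projected back onto the surface by ray casting; a frontal camera computed
    from the eye and mouth landmarks is refined twice before the final
    read-off. Also provides generalized Procrustes analysis of landmark
    configurations (centroid size, rigid alignment, Procrustes distance from
    the mean, observer-error reports), a locally-affine-regularized non-rigid
    iterative closest point (NICP) registration of an atlas mesh with dense
    atlas averaging, and a synthetic face-fixture generator with painted
    landmark markers and known ground truth for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
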
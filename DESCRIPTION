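Package: toothwear
Title: Simulation Modeling of the Tooth Wear Process on Triangle Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the gradual wear (attrition) of a tooth from two
    triangle meshes of the same crown, one intact and one worn, with
    arbitrary unequal tessellations. Anatomical feature points are found by
    quadric-error-metric mesh simplification, the two surfaces are rigidly
    aligned on the unworn axial walls by iterative closest point, a
    homogeneous wear surface with the intact mesh's connectivity is built
    from a radial-basis-function distance field and refined by a
    contraction-and-bounding iteration, and intermediate wear morphologies
    are reconstructed by bilinear interpolation of Laplacian differential
    coordinates with sparse least-squares reconstruction. Population
    attrition-index-by-age tables can be fitted with a cubic dynamic control
    function to drive nonlinear, age-realistic wear schedules. Includes a
    synthetic cusp-and-fossa tooth generator with known ground-truth wear
    fields, plain-text PLY/OBJ/STL mesh input and output, and per-vertex
    wear-depth maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
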
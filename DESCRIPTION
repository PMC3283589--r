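Package: squarecut
Title: Template-Constrained Graph-Cut Segmentation of 2D Grayscale Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-based segmentation of roughly rectangular objects in 2D
    grayscale images. Rays cast from a user seed point through a normalized
    closed polygon template define a non-uniform polar node grid; infinite
    intra- and inter-column arcs plus intensity-derived terminal arcs form a
    directed graph whose minimum s-t cut is a minimum-cost closed set, and the
    upper envelope of that set is the object contour. Includes contour
    smoothing, mask rasterization, Dice similarity evaluation, deterministic
    synthetic phantoms (rectangles with missing border parts, vertebra-like
    shapes with adjacent look-alike structures), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pracma,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
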
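Package: leafcut
Title: Surface-Following Virtual Cuts and Cell Morphometrics for Confocal Leaf Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multi-channel 3D confocal stacks of cereal leaf
    epidermis into a surface-following 2D "virtual cut", segments cells and
    nuclei by marker-controlled watershed, and extracts per-cell morphometric
    features (area, perimeter, best-fit-ellipse axes, elongation, circularity,
    rectangularity, lobeyness, neighbor counts, cell size index) together with
    cell and nucleus volumes.  Includes edge-preserving anisotropic diffusion,
    tile stitching, grayscale-morphology trichome removal on the leaf surface
    mask, programmatic label editing, cell-nucleus matching through a cylinder
    approximation of the epidermal layer, and a synthetic leaf-stack generator
    providing ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
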
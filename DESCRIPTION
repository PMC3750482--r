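Package: cellcontour
Title: Outline-Learning Segmentation of Cell Cytoplasm in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments cell cytoplasm in two-channel (actin/DNA) fluorescence
    microscopy images. Cytoplasm is first separated from background by a
    coefficient-of-variation enhancement of the Gaussian scale-space
    representation followed by Otsu thresholding. Cell-to-cell outlines are
    then detected by an L1-penalized logistic regression pixel classifier
    trained on a large generic bank of intensity, edge and texture features,
    and refined in a nuclei-guided post-processing step that splits and
    merges cytoplasmic regions into individual cells. Includes an
    object-level F-measure evaluation protocol and a synthetic two-channel
    image generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    tiff,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
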
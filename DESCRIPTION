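Package: bodycomp
Title: Automated L3 Slice Selection and CT Body-Composition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic selection of the third-lumbar (L3) axial slice from an
    abdominal CT volume and segmentation of that slice into skeletal muscle,
    visceral and subcutaneous adipose tissue, with derived sarcopenia metrics
    (muscle area, density, index, gauge and lean body mass). L3 localization is
    cast as 2-D segmentation of a coronal maximum-intensity projection and
    solved with a U-net trained under the dice loss; tissue maps are
    post-filtered by Hounsfield-unit windows. A synthetic abdominal-phantom
    generator with known ground truth (including arms-in-field and
    metal-implant variants) lets the whole pipeline be trained and validated
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    yaml
Config/testthat/edition: 3
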
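Package: toothfusion
Title: Tooth Model Reconstruction by Fusing Intraoral-Scan Crowns with CT Roots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reconstructs complete digital tooth models for computer-aided
    orthodontics by integrating two imaging modalities: high-resolution
    intraoral (laser) surface scans, which see only the crowns, and CT/CBCT
    volumes, which see the whole tooth but render the crown coarsely.
    Provides marker-based watershed segmentation of individual crowns from
    arch triangle meshes using an area+curvature edge height function,
    slice-propagated hybrid level-set segmentation of teeth from CT volumes
    with Radon-transform separation lines between neighbouring teeth,
    isosurface reconstruction, PCA coarse plus quaternion ICP fine rigid
    registration of the per-tooth models, Delaunay-based region-growing
    (DBRG) fusion of the laser crown with the CT root into a single surface,
    directed average-distance error metrics, and a synthetic dental phantom
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RANN,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
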
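Package: octmap
Title: Unsupervised Ordering of Anterior-Chamber OCT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully unsupervised pipeline that orders anterior-chamber optical
    coherence tomography (AS-OCT) images in a two-dimensional plane. Images are
    pre-processed (intensity normalization, resolution isotropization, median and
    Perona-Malik anisotropic-diffusion filtering, moment-based centering and
    principal-axis alignment), pairwise Hellinger or Euclidean distances are
    computed between aligned canvases, and the distance matrix is embedded in 2-D
    with IsoMap or t-SNE run directly on precomputed distances. Includes
    landmark-based clinical features (anterior chamber depth, iridocorneal angles,
    angle recess area ARA500) used to validate the ordering, a synthetic phantom
    generator with known ground-truth geometry for testing without clinical data,
    Image Map montage rendering, and a best-correlating-direction statistic that
    relates embedding coordinates to clinical features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    yaml,
    jsonlite,
    png,
    tiff,
    rlang,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    vegan,
    withr
Config/testthat/edition: 3
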
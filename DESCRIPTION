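Package: tractica
Title: Group Independent Component Analysis of Tractography Connectivity
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes whole-brain probabilistic-tractography connectivity
    matrices (grey-matter seeds by white-matter targets, streamline visitation
    counts) into paired grey-matter "node" maps and white-matter "edge" maps.
    Implements distance weighting and group averaging of count matrices,
    incremental groupwise PCA over the target dimension (MIGP), seed-domain
    FastICA with regression back-projection, Gaussian/gamma mixture-model
    thresholding of component maps, winner-take-all hard parcellation,
    split-half reliability against contiguous random (Voronoi) parcellation
    nulls, dual regression onto individual subjects with scalar component
    weights, Spearman covariate screening with Storey or Benjamini-Hochberg
    false-discovery-rate control, and spatial comparison of structural
    components against functional network maps. Includes a synthetic
    multi-subject generator with known ground truth for end-to-end
    parameter-recovery testing, and readers/writers for probtrackx2-style
    sparse triplet matrices, NIfTI volumes and GIFTI surface maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    generics,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
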
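Package: segfree
Title: Segmentation-Free Cell-Type Mapping for High-Resolution Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Grid-based analysis of in situ capture spatial
    transcriptomics without cell segmentation. Transcript counts are
    binned onto a pixel grid and smoothed per gene with precomputed
    truncated kernel masks (Gaussian or Epanechnikov); every pixel is
    classified by cosine similarity against a cell-type signature matrix,
    and a normalized assignment score quantifies the local confidence of
    the classification. Includes de novo signature construction from
    local maxima of the total-mRNA density, a synthetic-tissue simulator
    with known ground truth for validation, and writers for
    community-standard image and matrix formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    grDevices,
    jsonlite,
    Matrix,
    methods,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
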
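Package: msimaps
Title: Preprocessing and Spectral-Similarity Pseudocoloring for Mass
    Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless toolkit for MALDI mass spectrometry imaging (MSI)
    data. Reads and writes imzML, keeps datasets in an HDF5 pixel-table
    store, normalizes spectra (mean, median, median fold change), detects
    and subtracts chemical-matrix and artifact signals via a truncated-SVD
    plus UMAP pixel embedding, picks peaks on the winsorized mean spectrum
    with FWHM extents and optional deisotoping, and renders dynamic
    spectral-similarity pseudocolor maps (inverse angular distance on an
    8-bit byte representation) with browsing and grouping modes. Includes
    a synthetic phantom generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    rhdf5,
    uwot,
    irlba,
    matrixStats,
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
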
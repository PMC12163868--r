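Package: mcrfuse
Title: Multimodal Hyperspectral Image Fusion by Incomplete-Multiset MCR-ALS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unmixing of multimodal hyperspectral images that differ in
    scanned area and pixel size. Images from two or more modalities (e.g.
    whole-cell fluorescence emission stacks and small-area Raman maps) are
    preprocessed (spatial binning, cosmic-spike removal, SVD-Fourier
    denoising, asymmetric least squares baseline correction, spectral range
    selection), co-registered by exhaustive rigid shift-plus-rotation search
    on reference distribution maps, assembled into a single augmented
    multiset matrix containing explicitly masked missing blocks, and
    factored by multivariate curve resolution alternating least squares
    (MCR-ALS) with row-wise and column-wise least-squares updates restricted
    to observed entries. Constraints include non-negativity (clipping or
    true non-negative least squares), correspondence of species (zeroed
    concentration blocks) and equality-to-zero spectral segments. A
    synthetic labeled-cell phantom generator with known ground truth, a
    plain-text/TIFF I/O layer and a command-line pipeline are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
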
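Package: eashe
Title: Entropy-Based Adaptive Subhistogram Equalization for Image Contrast
    Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Contrast enhancement for 8-bit grayscale and RGB images by
    entropy-based adaptive subhistogram equalization. The intensity histogram
    is split into four entropy-balanced segments, each segment's output
    dynamic range is reallocated by an entropy-weighted blend toward the
    uniform share, the probability density is reshaped with a data-derived
    control factor, and each segment is equalized independently. Includes
    discrete entropy, PSNR and AMBE quality metrics, deterministic synthetic
    test-image generators, PNG/TIFF/PGM/PPM readers and writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
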
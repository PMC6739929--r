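Package: radtex
Title: Radiomic Texture and Shape Analysis of Lesion MRI with
    Discriminant-Based Subtype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible radiomics pipeline for single-slice lesion images
    with binary regions of interest: gray-level normalization limiting the
    dynamics to the ROI mean plus/minus three standard deviations, a
    352-feature MaZda-style extractor (first-order histogram, gray-level
    co-occurrence and run-length matrices, absolute gradient, 2-D
    autoregressive model, Haar wavelet energies, and lesion geometry), filter
    feature selection by Fisher ratio, probability of classification error
    with average correlation (POE+ACC), and mutual information, linear
    discriminant projection onto most-discriminating features, and k-nearest
    neighbor classification with leave-one-out cross-validation. Includes a
    seeded synthetic lesion-cohort generator with class-controlled interior
    texture and boundary shape, per-pixel sliding-window feature maps, and an
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
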
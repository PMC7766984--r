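Package: medfuse
Title: Multi-Modal Medical Image Fusion with a Dense-Feature-Reuse Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fuses registered structural (MRI-like) and pseudo-colour
    functional (PET/SPECT-like) brain images. Functional images are
    decomposed in the NTSC YIQ colour space so that only the luma channel is
    fused and chroma is preserved; both inputs are enhanced by an
    intuitionistic fuzzy preprocessing step whose exponent is selected by an
    entropy criterion; a small convolutional encoder with a single
    dense-feature-reuse layer and SeLU activations extracts feature stacks,
    which are combined with trace-derived convex weights and decoded back to
    an image.  The encoder/decoder pair is trained as an autoencoder with a
    mixed cross-entropy plus structural-similarity loss.  A ten-metric fusion
    quality suite (entropy, cross entropy, RMSE, average gradient, SSIM,
    feature mutual information, Qabf, Qw, Qe and visual information
    fidelity) and seeded phantom-pair generators make the whole pipeline
    testable without external image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
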
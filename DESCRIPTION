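Package: dropspec
Title: Rotation-Invariant Spectral Discrimination of Dried Droplet Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative discrimination of dried blood droplet photographs
    by rotation-invariant angular log-power-spectrum texture features.
    Implements the full image chain (red-channel extraction, crack detection
    and inpainting, Fourier-domain Gaussian low-pass, Laplacian magnitude,
    polar resampling, angular spectrum), a PCA-LDA discriminator with a
    centroid distance-ratio decision rule, a two-stage greedy search for the
    training participants that minimise the whole-cohort error rate, a
    synthetic droplet and blood-chemistry generator with known ground truth,
    and acid-base chemistry utilities (strong ion difference, hydrogen ion
    concentration, blood volume change).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    png,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
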
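Package: octpreset
Title: Unpaired Conversion of OCT B-Scans Between Scanning Presets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the unpaired mutual conversion of optical coherence
    tomography (OCT) B-scans between scanning presets that trade scanned
    area against per-image speckle averaging (the fast, noisy Macular Cube
    preset versus the slow, clean Seven Lines preset). Implements a
    contrastive unpaired translation GAN (encoder-decoder generator, patch
    discriminator, patchwise noise-contrastive estimation loss) trained
    entirely in R with Rcpp convolution kernels, referenceless image
    quality assessment (equivalent number of looks, contrast-to-noise
    ratio, BRISQUE natural-scene-statistics features), quality-driven
    checkpoint selection, an automatic preset-separability experiment, and
    a layered speckled-phantom simulator that generates synthetic training
    data with the statistical structure of the two presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
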
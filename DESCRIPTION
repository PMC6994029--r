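Package: picover
Title: Pigment Cover Quantification for Chromatophore Dispersion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures pigment cover (PiC), the fraction of a region of
    interest occupied by pigmented chromatophores or chromatosomes, from
    digital images of animal tissue photographed on a uniform background.
    Provides HSB colour-band segmentation with automatic histogram
    thresholding (IsoData iterative intermeans and Kapur maximum-entropy),
    connected-component particle analysis, transparency measurement on
    chromatic backgrounds, the Hogben-Slome chromatophore index (CI), and a
    beta-regression layer with link selection by AIC for relating PiC to CI.
    A seeded synthetic chromatosome scene generator with exact ground-truth
    cover supports end-to-end validation of the measurement pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    stats,
    tools,
    utils,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
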
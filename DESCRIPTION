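Package: pseudonir
Title: Pseudo-NIR Estimation from RGB Imagery via GNDVI-Guided Green Channel
    Adjustment and a Multi-Scale Encoder-Decoder Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates near-infrared (NIR) reflectance bands from standard RGB
    images. Implements the GNDVI-guided G-RGB transformation (a clamped linear
    green-channel shift toward a pseudo-NIR value 2G - R), vegetation index maps
    (NDVI, GNDVI, NDWI), PCA cumulative-loading band selection over the NIR
    range of hyperspectral cubes, reconstruction quality metrics (MSE, PSNR,
    SCC, SSIM, MAE/RMSE, histogram similarity), and FUSE-Net, a U-Net style
    encoder-decoder with CBAM attention, an MLP channel mixer and a multi-scale
    convolutional bottleneck, trained with Adam, learning-rate plateau halving
    and early stopping. A synthetic scene generator produces paired RGB and
    hyperspectral reflectance cubes with vegetation-like red-edge spectra so
    the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jpeg
Config/testthat/edition: 3
RoxygenNote: 7.3.3
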
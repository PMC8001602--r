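Package: nglseg
Title: Sparse-Enhanced Shallow Encoder-Decoder Segmentation of Newly
    Grown Leaves in Very-High-Resolution Canopy Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects rare, tiny newly-grown-leaf (NGL) targets in
    very-high-resolution RGB vegetation imagery. Implements sparse
    enhancement preprocessing based on robust principal component
    analysis (GoDec and convex principal component pursuit kernels,
    E = P + S), a family of shallow hybrid encoder-decoder segmentation
    networks with reduced pooling depth and skip connections (SegNet and
    U-Net baselines plus 3L-SN, 3L-USN, 2L-USN and 2L-Conv-USN), the
    class-imbalance-aware cross-entropy losses (CE, WCE, BCE), sliding
    window patch extraction and prediction stitching, error-matrix
    metrics (accuracy, ROC/AUC, Cohen's kappa, tri-color result maps),
    a seeded synthetic canopy scene generator, and an end-to-end
    experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    e1071,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
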
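Package: RFStacks
Title: Random Forest Stacks for Membrane Segmentation in Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise segmentation of ribbon-like membrane structures
    (such as the glomerular basement membrane) in transmission electron
    microscopy images using a two-level random-forest ensemble. Training
    images are stratified into contiguous grayscale groups; a full-view
    forest is trained on pixels pooled across all groups while a zoom-view
    bank holds one forest per group. At test time the zoom-view coarse
    results are fused through a per-pixel probability map, bipartitioned
    with fuzzy C-means, cleaned morphologically and refined iteratively.
    Includes a synthetic image generator emulating membrane morphologies
    and grayscale diversity, Jaccard-based evaluation utilities, a
    cross-grayscale heat-map benchmark and an ablation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    ranger,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    tiff,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Segmentation, Classification
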
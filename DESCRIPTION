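Package: GLRLMtexture
Title: Gray Level Run Length Matrix Texture Features for Sliding-Window
    Image Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes gray level run length matrices (GLRLMs) and the
    eleven classical run-length texture features (SRE, LRE, GLN, RLN, RP,
    LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE) for every sliding rectangular
    region of interest of a 2-D grayscale image, along the four principal
    directions. Three mutually validating engines are provided: a per-ROI
    brute-force construction, an optimized sequential engine built on a
    whole-image run length array, and a batch engine that encodes
    (ROI, gray level, run length) triples into sortable integer keys and
    builds all sparse matrices at once by scatter, reduce-by-key and sort
    primitives. Includes deterministic synthetic image generators, an
    embedded worked example with its published four-direction matrices,
    readers for PNG/PGM/CSV images, writers for sparse triplets and dense
    feature maps, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    png,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: ImageProcessing, FeatureExtraction, Software
RoxygenNote: 7.3.3
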
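Package: fibrarch
Title: Quantification of Fibrillar Collagen Architecture and Matrisome
    Dynamics from Microscopy and Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying fibrillar-collagen architecture in
    microscopy images and matrisome dynamics in label-free proteomics.
    Implements second-harmonic-generation (SHG) peak-signal and
    fibre-bundle-width measurement, grey-level co-occurrence matrix
    (GLCM) Haralick-correlation texture curves, structure-tensor
    orientation fields with peak-to-baseline alignment ratios,
    hue-saturation-brightness (HSB) stain segmentation for picrosirius
    red, birefringence hue classes and DAB, closed-form study
    morphometrics (invasive index, tumour volume, metastasis burden,
    compressive elastic modulus), and a temporal proteomics pipeline
    (presence filtering, log2 median-centring, row-wise ANOVA and Welch
    tests with Benjamini-Hochberg control, hierarchical temporal
    clustering, Fisher category enrichment, PCA). A synthetic-data
    module generates fibre phantoms, stained-slide phantoms, abundance
    matrices with planted temporal clusters and stress-strain curves
    with known ground truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
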
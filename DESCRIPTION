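Package: epimorph
Title: Quantitative Analysis of Epithelial Morphogenesis from Tracked Cell Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify convergence and extension of epithelial tissues
    from time-lapse movies of tracked cells, built around Drosophila germband
    extension. Implements strain-rate decomposition of tissue deformation into
    cell-shape change and cell intercalation, T1 neighbour-exchange detection
    with a continuous productivity score, junctional Myosin II planar-polarity
    (bipolarity) quantification by Fourier analysis with cell unstretching,
    movie synchronisation to the onset of axis extension, and per-time-bin
    mixed-effects comparison of genotypes. Includes a synthetic-embryo
    generator with prescribed flows, scripted neighbour exchanges and rendered
    two-channel images, providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    lmerTest,
    tiff
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
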
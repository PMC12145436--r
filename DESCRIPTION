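Package: geokrig
Title: Multiresolution Lattice Kriging of Cortical Surface Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spatial Gaussian-process prediction (lattice kriging) of scalar
    maps on spherical cortical surface projections and planar imaging grids,
    using multiresolution compactly supported Wendland basis functions with a
    sparse spatial-autoregressive coefficient prior. Includes extreme-tail
    masking and out-of-mask evaluation of task-contrast maps, pairwise
    task-specificity tests on conjunction masks, network-mask prediction with
    spin-rotation permutation nulls, eigenmode-rotation ("eigenstrapping")
    surrogate maps with preserved spatial autocorrelation, a planar variant
    for widefield calcium-imaging frame series with Fisher-z and
    autoregressive group inference, and seeded synthetic-data generators
    (autocorrelated spherical maps, task families, network parcellations,
    smooth movies) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
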
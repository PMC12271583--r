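Package: cryolabel
Title: Voxel-Aligned Label Maps and Map-Model FSC for Cryo-EM Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates supervised-learning label maps from experimental
    cryo-EM density maps and their atomic biological assemblies: standardizes
    maps to a 1 Angstrom voxel grid, simulates idealized noise-free density by
    real-space Gaussian convolution of atomic coordinates, and produces three
    voxel-aligned label maps (density regression, structure/background
    classification, and atom-type classification) using a floor-based
    coordinate-to-index transform with 6 Angstrom neighborhood labeling.
    Includes bit-level MRC2014 reading and writing with axis-order and origin
    normalization, biological-assembly PDB parsing, unmasked map-model Fourier
    Shell Correlation with resolution extraction at the 0.5 and 0.143
    thresholds, dataset curation filters, synthetic desk-scale fixtures, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
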
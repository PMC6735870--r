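Package: cbmapr
Title: Competitive-Binding Optical DNA Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis for competitive-binding optical DNA mapping.
    Predicts sequence-dependent fluorescence barcodes from DNA sequence using a
    two-species (netropsin/YOYO-1) lattice binding model and the microscope
    point-spread function, reduces kymographs to time-averaged experimental
    barcodes, places barcodes on reference genomes by sliding Pearson
    correlation over position, orientation and stretch, assigns extreme-value
    P-values against a randomized-sequence null, quantifies genome mappability
    by fragmentation simulation, and projects second-channel (DNA damage)
    signals onto genome coordinates. A synthetic-data module generates genomes,
    planted fragments and simulated kymographs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    tibble,
    dplyr,
    purrr,
    readr,
    generics,
    withr,
    yaml,
    jsonlite,
    ggplot2,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
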
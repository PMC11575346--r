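Package: dormaquant
Title: Quantifying Bacterial Dormancy from Single-Cell Images, Colony
    Time-Lapses and Aggregate Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying dormancy-associated phenotypes of
    Escherichia coli persister cells: counting fluorescent protein-aggregate
    foci per cell from phase-contrast/fluorescence image pairs, extracting
    colony appearance and growth times from flatbed-scanner time-lapse stacks
    (ScanLag), constructing toxin-dependent protein-aggregate sets from
    replicate label-free proteomics intensity tables (Welch t-test with
    Benjamini-Hochberg control plus exclusive-presence rules), and small
    quantification formulas (Pfaffl fold change, ATP calibration, relative
    CFU). Seeded synthetic-data generators for all three modalities provide
    machine-readable ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
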
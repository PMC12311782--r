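Package: dmscreen
Title: Analysis, Comparison and Simulation of DMS Mutational Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A harmonized data model for chemical-probing mutation profiles
    (DMS-MaPseq and related mutational-profiling experiments), statistics for
    comparing per-nucleotide reactivity profiles across samples and conditions,
    a correlation-based screen for ligand-responsive RNAs such as riboswitches,
    declarative plot builders with CSV/PNG/HTML export, converters for
    ShapeMapper2 and RNA Framework outputs, and a barcoded amplicon library
    designer with a read-level DMS signal simulator so every analysis step is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
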
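Package: sumostress
Title: Differential Sumoylation, Expression and Inclusion Analysis for
    Hyperosmotic Stress Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for quantifying rapid, stress-dependent
    protein sumoylation and its downstream consequences in budding yeast.
    Implements spectral-count differential-enrichment calling from
    peptide identification tables, empirical-null thresholding and
    mutant-effect analysis of two-color expression arrays (including
    detection and masking of aneuploid chromosome segments and
    average-linkage clustering with uncentered correlation), and
    quantification of fluorescence inclusions, nuclear enrichment and
    two-channel colocalization from labeled cell images. Synthetic-data
    generators with known ground truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
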
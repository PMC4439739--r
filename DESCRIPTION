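Package: micoskit
Title: Interaction Proteomics and Complexome Profiling of the MICOS Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses for characterising inner-membrane protein
    complexes such as the mitochondrial contact site and cristae organizing
    system (MICOS). Implements CompPASS-style scoring of affinity
    purification-mass spectrometry (AP-MS) spectral-count data (WD, NWD and
    z-scores against a multi-bait background stats table), filtering of
    high-confidence interacting proteins and assembly of multi-bait
    interaction networks; SILAC blue-native PAGE complexome profiling with
    per-fraction heavy:light ratios, gel-slice mass calibration and detection
    of complex-disassembly shifts; and spatial enrichment analysis of
    immunogold particles relative to cristae junctions with a Monte-Carlo
    test against a uniform-along-membrane null. Seeded synthetic-data
    generators with known ground truth accompany each analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
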
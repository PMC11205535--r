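Package: nucleoid3d
Title: 3D Genome Architecture of the Bacterial Nucleoid from 3C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the three-dimensional organisation of
    circular bacterial chromosomes from chromosome-conformation-capture
    (3C/Hi-C) contact matrices: SCN matrix balancing, distance-decay and
    short-range interaction summaries, directionality-index based calling
    of chromosome interaction domains (CIDs), global and local compactness
    metrics on 3D chromosome models, correlation of chromosome structure
    with binned transcription, nucleoid image morphometry, and a
    synthetic-data generator with planted ground truth so that every
    pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    bio3d,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
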
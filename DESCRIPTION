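Package: offcontext
Title: Detection of Ectopic (Off-Context) Gene Expression from Tissue Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes as tissue-restricted or tissue-predominant with
    respect to germline, placenta and embryonic stem cell classes from a
    multi-tissue reference expression atlas, then detects their ectopic
    activation in case samples relative to controls using per-gene
    mean + k * SD thresholds. Includes cross-dataset concordance reporting,
    a seeded synthetic-data generator with planted ground truth for
    calibration and recovery experiments, and readers/writers for
    TSV/CSV/GCT expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
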
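Package: hormonomics
Title: Untargeted Phytohormone Screening for LC-MS Peak Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Annotates untargeted liquid chromatography-mass spectrometry
    (LC-MS) peak tables against a curated database of plant growth
    regulators (phytohormones), their precursors, conjugates and
    metabolites. A compound catalogue is expanded in silico by common
    electrospray adducts and by synthetic biotransformation mass shifts
    (methylation, hydroxylation, glycosylation, amination, carboxylation
    and their reversals), features are matched on m/z within a Dalton or
    ppm tolerance and ranked by closeness of the observed retention time
    to a predicted retention time. Includes a random-forest retention-time
    regressor trained on physicochemical descriptors, a meta-analysis
    pipeline with gradient-dependent retention filtering and class-binned
    summaries, a synthetic peak-table generator with known ground truth
    for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
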
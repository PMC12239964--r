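Package: spcdopa
Title: Simulation and Analysis of Striatal Dopamine Photometry in Sensory
    Preconditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analyzing two-channel (470 nm active / 415 nm
    isosbestic) fiber photometry recordings from a three-phase sensory
    preconditioning task, together with a synthetic-data generator that
    simulates the task end to end. The analysis chain implements median
    filtering, polynomial isosbestic motion correction, per-trial baseline
    z-scoring and session peak normalization, peri-event alignment, peak and
    area-under-curve quantification, food-port occupancy, discrimination
    indices, and exact small-sample nonparametric tests. The generator couples
    a delta-rule model of cue-cue and cue-reward learning to a double
    exponential sensor kernel with photobleaching, shared motion artifacts and
    noise, retaining all ground-truth latents so every pipeline stage can be
    validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    dplyr,
    jsonlite,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
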
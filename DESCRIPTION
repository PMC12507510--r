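Package: odorplace
Title: Population Coding of Odor and Place in Miniscope Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing odor and place information in segmented
    one-photon calcium-imaging recordings from olfactory cortical areas.
    Builds trial-aligned, z-scored activity tensors from raw fluorescence
    traces and behavioural event tables; quantifies single-cell odor
    responsiveness, magnitude and duration; computes trial-by-trial
    population-vector similarity matrices; performs time-resolved odor
    identity decoding with leave-one-trial-out linear support vector
    machines, binomial significance series and ensemble-size subsampling;
    and decodes position on a linear track with a maximum-correlation
    decoder, including direction-specific versus trajectory-phase analyses
    of the spatial code. A synthetic-data generator with known ground truth
    emulates head-fixed and freely-moving session designs so that every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    graphics,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
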
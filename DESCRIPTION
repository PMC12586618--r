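Package: artikin
Title: Articulatory Kinematics from Real-Time Vocal-Tract MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extraction and statistical analysis of articulator kinematics from
    midsagittal real-time MRI image sequences of speech. Builds anatomical
    measurement-line grids, extracts space-by-time intensity line profiles,
    segments air from tissue with a constrained three-component Gaussian
    mixture model, tracks articulator gaps over time, normalizes trajectory
    durations to the cohort median, fits penalized function-on-scalar
    regression models of movement curves on group with time-varying subject
    effects, and clusters speakers by energy distances between
    inter-articulator spatiotemporal dissimilarities (Simpson-rule L2 metric),
    with C-index cluster-number selection, Fisher exact testing and principal
    component analysis. Includes a synthetic vocal-tract phantom generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    mgcv,
    jsonlite,
    yaml,
    tiff,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
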
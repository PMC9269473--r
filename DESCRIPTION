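Package: kurtoseg
Title: Stationarity-Driven Segment-Length Selection and Directed
    Connectivity for Multichannel EEG
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects the multivariate autoregressive (MVAR) segment length
    for resting-state EEG effective-connectivity analysis from the signals'
    own stationarity profile. Each channel is iteratively split into
    non-overlapping windows at integer multiples of a basis duration,
    per-segment excess kurtosis scores short-time departures from
    Gaussianity, and the variance of those kurtosis profiles over window
    length defines a search domain in which a density-guided interval
    search finds the shortest duration shared by most channels. The
    selected window then drives a complete directed-connectivity pipeline:
    per-segment MVAR fits, the squared Directed Transfer Function (DTF) on
    a 1 Hz grid, band-averaged significance-masked adjacency matrices, and
    cost-thresholded directed graph metrics (degree, density, strength,
    path length, efficiencies, clustering, betweenness). Includes EDF and
    delimited readers, the resample/band-pass/common-average-reference
    conditioning chain, cohort retention filtering, and seeded synthetic
    generators with ground-truth coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'graph.R'
    'io.R'
    'kurtoseg-package.R'
    'methods.R'
    'mvar-dtf.R'
    'pipeline.R'
    'preprocess.R'
    'segmentation.R'
    'synthetic.R'
    'window-selection.R'
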
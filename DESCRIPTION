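Package: lamsel
Title: Laminar Population Selection Analysis for Visual Cortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for laminar multielectrode recordings from
    visual cortex during pop-out search. Provides multiunit envelope
    extraction and baseline normalization, current source density (CSD)
    estimation with functional laminar alignment on the granular input
    sink, the Monte-Carlo population reliability (winner-take-all)
    selection statistic with empirical chance calibration, Bayesian
    power-function regression of reaction time on feedforward population
    responses, reaction-time binning and priming-block analyses, cone
    contrast colorimetry for stimulus calibration, and a synthetic laminar
    session generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    coda,
    jsonlite
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'behavior-priming.R'
    'colorimetry.R'
    'lamsel-package.R'
    'methods-accessors.R'
    'population-reliability.R'
    'rt-power-model.R'
    'session-io.R'
    'signal-processing.R'
    'synthetic-session.R'
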
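Package: ddasim
Title: Simulation and Evaluation of Data-Dependent Acquisition Strategies
    for Multi-Sample LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual liquid-chromatography tandem mass-spectrometry
    instrument for developing and benchmarking real-time data-dependent
    acquisition (DDA) scan-prioritization strategies across multi-injection,
    multi-sample experiments. Implements a family of TopN-style controllers
    sharing one parametric scoring function -- from classic TopN with dynamic
    exclusion windows through region-of-interest (RoI) based multi-sample
    exclusion, intensity exclusion, and rectangle-overlap (non-overlap and
    intensity non-overlap) area weighting. Includes centwave-style real-time
    RoI tracking, an exclusion-window registry with within- and
    between-injection lifetimes, an exact axis-aligned rectangle dissection
    kernel, a seeded generator of ground-truth multi-sample chemical
    mixtures with aligned picked-peak boxes, cumulative peak-coverage and
    intensity-coverage metrics, and mzML/CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    mzR,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
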
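Package: sensikit
Title: Quantitative Analysis of Sensory Neuron Sensitization Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the three quantitative arms of in vitro sensory
    neuron sensitization experiments. Converts ROI fluorescence traces from
    calcium imaging into dF/F, gates live cells by a terminal KCl
    depolarisation criterion and classifies drug responders; quantifies
    culture purity from multi-channel immunofluorescence stacks by nucleus
    counting with area-to-count correction and pairwise colocalization;
    extracts the current-clamp feature battery (resting membrane potential,
    rheobase, action potential threshold, amplitude, half-width, fast and
    medium afterhyperpolarisation, firing pattern, exclusion rules) from
    sweep recordings. Ships a normality-gated two-group statistical battery
    with a Bonferroni family ledger and a literature
    resting-membrane-potential synthesis, plus seeded synthetic-data
    generators (fluorescence trace cohorts, labelled nuclei images, adaptive
    exponential integrate-and-fire recordings) with machine-readable ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
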
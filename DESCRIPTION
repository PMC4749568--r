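Package: sigold
Title: Simulation and Analysis of Serial-Multiplex Immunogold Labeling for
    Connectomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing serial-multiplex immunogold
    (siGOLD) experiments, in which sparse subsets of serial ultrathin EM
    sections are each labeled with one neuropeptide antibody and molecular
    identities are propagated to fully traced neurons. Provides a generative
    simulator of serial-section datasets (bursty dense-core-vesicle occupancy
    along neurites, sparse labeling designs, thinned-Poisson gold deposition,
    vesicle-diameter models), gold-count tabulation and candidate selection,
    rule-based identity calling with coexpression and cross-reactivity
    analysis, power analysis of labeling designs, synapse-count circuit graph
    construction from skeletons and connectors, and iterative unbiased
    average-template construction for image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
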
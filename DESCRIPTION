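Package: lmnet
Title: Functional Connectivity and Hub Disruption Analysis for a
    Language-and-Memory Brain Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state functional-connectivity analysis over a 72-node
    language-and-memory network: denoising of ROI BOLD time series (outlier
    scan detection, component-based confound regression, band-pass
    filtering), pairwise Pearson/Fisher-z connectivity with edge-wise Welch
    group statistics under Bonferroni and FDR correction, binary graph
    efficiency metrics (global, nodal, local) at proportional connection
    costs with a small-world control, the hub disruption index, and
    cognition-connectivity correlation. Includes a synthetic BOLD cohort
    generator with planted limbic hyperconnectivity and remote cortical
    hypoconnectivity effects, and a packaged per-patient clinical and
    neuropsychological data table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
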
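Package: lpmgem
Title: Transcriptome-Constrained Flux Balance Analysis with Loop Removal
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modelling that embeds continuous
    gene-expression values into flux balance analysis. Expression is mapped
    linearly onto feasible flux ranges obtained from flux variability
    analysis, and fluxes are fitted by a weighted L1 objective under
    steady-state, bound, biomass-floor and exchange-cap constraints. Three
    strategies suppress thermodynamically infeasible loops: iterative
    feasible flux space reduction (bound halving accepted while the mapping
    discrepancy decreases), iterative minimum-cardinality loop detection and
    exclusion via mixed-integer cuts, and an L1 flux penalty. Downstream,
    carbon sources are called from cross-condition z-scores of transporter
    uptake fluxes. Includes readers for SBML/FBC, BiGG-style JSON and a plain
    TSV model dialect, a synthetic scenario generator, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
SystemRequirements: python (>= 3.8) with numpy and scipy (HiGHS backend)
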
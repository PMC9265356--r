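Package: pleconflict
Title: Production-Living-Ecological Space Conflict Assessment and
    Multi-Scenario Land-Use Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring land-use conflict in
    production-living-ecological (PLE) space and projecting its evolution
    under planning scenarios. Reclassifies six-class land-use rasters into
    four PLE space types, computes a grid-based spatial conflict composite
    index (shape complexity via the area-weighted mean patch fractal
    dimension, area-weighted vulnerability, and patch-density stability),
    simulates future land use with a Markov demand projection coupled to a
    neural-network-suitability cellular automaton with adaptive inertia,
    neighborhood effects and conversion-cost constraints, and derives
    conflict-transition functional zones. A synthetic-landscape generator
    produces autocorrelated categorical rasters with known transition
    structure and correlated drivers so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
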
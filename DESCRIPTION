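Package: chemorg
Title: Chemical Organization Analysis and Organization-Oriented
    Coarse-Graining of Reaction Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for organization-oriented coarse-graining of chemical
    reaction networks.  Implements static chemical organization theory
    (closure, self-maintenance via linear-programming flux feasibility,
    organization enumeration and Hasse lattices, boolean filtering of
    biologically meaningful organizations), discrete-organization analysis
    of the bounded-population continuous-time Markov chain of a network
    (strongly connected component decomposition, good and bottom
    components, expected leaving times, organization-level coarse-grained
    chains), exact stochastic trajectory simulation, a quasi-spatial
    four-state kinetochore checkpoint simulator, and compartment-level
    spatial organization mapping.  The spindle assembly checkpoint (SAC)
    model hierarchy is bundled as editable fixture networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
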
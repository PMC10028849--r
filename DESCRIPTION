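Package: mutnet3d
Title: Spatial Clustering of Somatic Mutations on Protein Structures with
    Network Heat Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies three-dimensional clusters of somatic in-frame
    mutations on single-protein structures and protein-protein interaction
    interfaces, scores them against a covariate-aware local background
    mutation model with Poisson recurrence tests, and propagates cluster
    and loss-of-function signals through a protein-protein interaction
    network using an insulated heat-diffusion model to call significantly
    interconnected modules. Includes deterministic synthetic-data
    generators (structures, cohorts, networks) so the full pipeline can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    igraph,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
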
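Package: paleoppin
Title: Reconstruction and Growth Dynamics of Ancient Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs ancestral protein-protein interaction (PPI) networks
    from scored present-day interaction data and orthologous-group assignments,
    and infers the growth dynamics of the reconstructed series. Provides
    percolation-based score thresholding of weighted interaction tables,
    Maximum-Excluded-Mass-Burning (MEMB) box covering with fractal dimension,
    renormalization-flow phase classification and modularity scaling, a
    stochastic duplication-divergence model with binomial-mixture likelihood
    fitting and ancestral-link posteriors, explicit level-by-level ancestral
    network reconstruction with fractal-dimension-calibrated probability
    cutoffs, multiplicative growth-rate estimation with static/dynamic
    consistency checks, and a forward duplication-divergence simulator with
    lineage tracking for validation with known ground truth.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
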
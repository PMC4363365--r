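Package: abnet
Title: Antibody-Reactivity Networks from Binary Immunoblot Band Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds significance-thresholded Pearson (phi) correlation
    networks among immunoblot antigen bands scored present/absent across a
    cohort of sera, computes network attributes (links, density, diameter,
    degree statistics, hubs), per-node connection-intensity statistics
    (N, M, I = N x M) with intensity ranking, and inter-group link-loss
    (disconnection) ledgers. Includes a seeded Gaussian-copula generator of
    correlated binary cohorts for calibration and testing, rank-based
    group comparisons, and plain-text fixtures of the published reference
    tables for consistency checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
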
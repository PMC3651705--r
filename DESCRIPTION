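Package: otip
Title: Optimal Tubulin Isotype Profiles for Side-Effect-Constrained Drug Design
Version: 0.1.0
Authors@R:
    person("OTIP", "Maintainers", email = "otip@example.org", role = c("aut", "cre"))
Description: Tools for computing the drug binding-affinity profile over the
    eight canonical human beta-tubulin isotypes that maximizes damage to a
    cancer cell type while capping the damage inflicted on each healthy
    tissue.  Implements dot-product and Kullback-Leibler damage models, a
    linear-programming profile optimizer with per-tissue damage caps, a
    penalized (net-benefit) variant, Boltzmann conversion of per-isotype
    binding free energies into affinity profiles, convex drug-combination
    algebra, a tissue/route/patient weighting model, screening of candidate
    drugs against tissue constraints, deterministic synthetic-profile
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
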
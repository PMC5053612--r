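Package: helpmarket
Title: Competitive Helping in Biological Markets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying competitive helping in a biological market in
    which individuals compete for the help dispensed by others.  Help is
    allocated by a matching-law rule with a tunable degree of matching and an
    optional level of costless passive help; fitness combines a saturating
    benefit of help received with a linear cost of help provided.  The package
    provides the closed-form optimal help levels and their stability analysis
    under two-type replicator dynamics, numerical integration of the replicator
    equations, an incremental-mutation agent-based simulator for two
    homogeneous types (with fixed or payoff-driven evolving proportions,
    basin-of-attraction maps and proportion sweeps), a fully heterogeneous
    N-person simulator with a passive-help sweep, and a reproducible scenario
    layer with seeded runs, CSV export and JSON run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
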
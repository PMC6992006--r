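Package: ugnorm
Title: Evolution of Egalitarian Norms in the Ultimatum Game with Adaptive
    Resource Management
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based and mean-field tools for studying how egalitarian
    social norms (high offers, high acceptance thresholds, empathy and
    conformity) evolve in the continuous Ultimatum Game when interacting
    pairs adaptively reallocate resources towards previously successful
    deals. Provides the pairwise deal/payoff machinery with a one-step deal
    ledger, synchronous Fermi (pairwise-comparison) norm updating with
    exploration and learning error, an optional coevolutionary process for
    the per-agent resource-management intensity, population observables
    (fairness, empathy, collective conformity), and a two-norm mini-game
    replicator analysis with basins of attraction and dominance thresholds.
    Includes a fast C++ engine, a matching pure-R reference engine, and a
    small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
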
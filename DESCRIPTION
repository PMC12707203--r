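Package: wslscommons
Title: Win-Stay Lose-Shift Self-Organization of Common-Good Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and simulates populations of users distributing themselves
    over congestible common goods with a Win-Stay, Lose-Shift (WSLS) strategy.
    Provides analytic M/M/c/k quality models (loss and timeout-exceedance
    probabilities), mean-field population dynamics with equilibrium solvers
    for homogeneous and tolerance-typed populations, the equalized-quality
    ideal distribution with tolerance-vector design and hybrid-population
    theory, and a seeded discrete-event agent simulator with fixed or
    adaptive per-good failure tolerance, applied to server selection in
    mobile-network Internet services.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
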
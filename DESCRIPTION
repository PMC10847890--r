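Package: closekin
Title: Close-Kin Mark-Recapture Simulation and Bayesian Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A close-kin mark-recapture (CKMR) toolkit for long-lived,
    intermittently breeding species. Provides a stochastic individual-based
    population simulator with full pedigree tracking (overlapping generations,
    stage-structured survival, annual to triennial female breeding cycles with
    off-cycle breeding), age-selective sampling with length-based aging error
    under a von Bertalanffy growth model, construction of grouped pairwise
    half-sibling and parent-offspring comparison matrices, closed-form kinship
    probability models (base case, exponential population growth, and
    multiennial breeding variants), and Bayesian estimation of abundance,
    survival, population growth rate and breeding periodicity by adaptive
    Markov chain Monte Carlo with Gelman-Rubin convergence gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
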
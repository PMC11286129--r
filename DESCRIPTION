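Package: pleionet
Title: Coevolution of Hosts with Pleiotropic Signalling Networks and
    Immune-Disrupting Parasites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of coevolution between hosts built from
    paired immune and developmental signalling networks -- either fully
    independent or sharing a single pleiotropic effector -- and parasites
    that disrupt host immune signalling. Implements resource-capped
    activation dynamics on signed regulatory networks, a full host life
    cycle (equilibration, pulsed developmental signalling, infection,
    fitness from effector, parasite and developmental-tracking costs),
    fitness-weighted death and reproduction with network mutation,
    two-phase competitive simulations between host architectures, and
    post-simulation analyses: single-knockout robustness, evolved network
    features, quasi-binomial regression of competition outcomes, and
    geometric mean fitness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
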
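Package: netcoop
Title: Cooperation and Cheater Invasion on Evolving Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulator of a fixed-size population playing the
    prisoner's dilemma on an evolving graph. Newcomers integrate by copying a
    fitness-selected role model and deciding which of its neighbours to attach
    to by fusing private information (noisy Gaussian perception of partner
    intent, thresholded at tau) with public information (a candidate's
    degree, betweenness or eigenvector centrality compared with the network
    average, or a random indication). Provides the perturbation protocol that
    mutates one individual to defection after a burn-in and measures recovery
    versus invasion outcomes, resolution times, pre-invasion prosperity
    metrics, batch aggregation, parameter sweeps and a prosperity-stability
    trade-off score.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
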
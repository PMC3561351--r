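Package: phasenet
Title: Phase-Synchrony Functional Brain Networks, Community Structure and
    Subject Classification
Version: 0.1.0
Authors@R:
    person("phasenet", "developers", email = "phasenet@example.org",
           role = c("aut", "cre"))
Description: Builds weighted functional connectivity networks from regional
    time series using a time-averaged phase-synchrony degree (the
    phase-locking value of Hilbert-transform instantaneous phases), as an
    alternative to Pearson correlation networks.  Provides edge-wise
    one-tailed two-sample t-tests yielding group statistical difference
    networks, modularity-maximization community detection with per-size
    modularity curves, within-community degree z-scores and inter-community
    connectivity ratios with a six-class node-role taxonomy, binary-graph
    metrics (cost, clustering coefficient, local and global efficiency),
    Lloyd k-means clustering of subjects on the modularity statistic with a
    bijection-maximized accuracy rate, threshold-sweep experiment drivers,
    and a synthetic two-cohort coupled-phase-oscillator generator with a
    planted "additional network" so the whole pipeline is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
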
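Package: centroclust
Title: Agent-Based Simulation and Quantification of Motor-Driven
    Centrosomal Condensate Clustering
Version: 0.1.0
Authors@R:
    person("Centroclust", "Developers", email = "maintainer@centroclust.org",
           role = c("aut", "cre"))
Description: Tools to study how minus-end-directed kinesin-14 (HSET/KIFC1)
    motors cluster pericentriolar-material condensates on microtubule
    networks. Provides a 2-D overdamped Brownian-dynamics simulator of
    semiflexible microtubules, bivalent motor couplers and motile
    condensate complexes with a two-phase bundling/clustering protocol;
    a short-distance clustering statistic with parameter-sweep heatmaps;
    kymograph-style track analysis (processive/diffusive event
    classification, velocity, run length, event rates); FRAP trace
    normalization and single-exponential recovery fitting (half-time,
    mobile/immobile fractions); condensate image quantification (droplet
    detection, partition coefficient, phase-diagram classification); and
    seeded synthetic-data generators with ground-truth labels so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
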
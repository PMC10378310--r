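Package: spreadsel
Title: Two-Phase Centrality Feature Selection for Influential Epidemic
    Spreaders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies influential epidemic spreaders in complex networks
    by combining Monte-Carlo SIR simulation with supervised feature
    selection over structural centralities.  Provides generators for
    Barabasi-Albert, Erdos-Renyi and Watts-Strogatz networks and an
    edge-list reader; nine node centralities (degree, one- and two-hop
    neighbourhood sums, k-shell, clustering coefficient, betweenness,
    closeness, eigenvector, PageRank); discrete-time SIR dynamics with
    epidemic-threshold estimation via the variability measure; top-f
    outbreak-size labelling; a two-phase feature-selection method
    (undersampled SVM-RFE-CV ensemble voting followed by correlation-based
    feature clustering with ReliefF); and an evaluation harness with
    single-centrality and alternative-selection baselines reporting
    Precision, Recall and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
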
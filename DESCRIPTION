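Package: rlcomplex
Title: Protein Complex Detection on Weighted Interaction Networks by
    Tabular Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects protein complexes (communities) in weighted
    protein-protein interaction networks with a single-agent
    reinforcement-learning pipeline. A tabular value-iteration agent learns
    a map from subgraph density to value by replaying growth episodes over
    known (gold-standard) complexes; a distributed seed-and-extend
    prediction step then grows one candidate complex per seed edge using
    only value-table lookups. Includes gold-standard preprocessing
    (size/connectivity filters and Jaccard merging), Qi-overlap
    post-processing with an F-score-driven threshold sweep, a full suite of
    cluster-versus-gold evaluation metrics (maximal-matching F-score,
    community-wise maximum F-score, Sn-PPV accuracies, Qi et al. F-score
    and k-clique F-scores), a planted-complex synthetic network generator,
    and an end-to-end command-line pipeline with value-table persistence
    for transfer learning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
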
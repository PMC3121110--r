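Package: netsynergy
Title: Network-Target Scoring and Ranking of Synergistic Agent Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes pairs of pharmacological agents (compounds, herbs,
    extracts) for likely synergy against a disease-specific background
    network. A topology score weighs each agent's genes by a PCA-integrated
    node-importance measure (betweenness, harmonic closeness, PageRank) and
    decays exponentially with the minimum shortest-path distance between the
    two gene sets; an agent score averages phenotype similarity over all
    cross pairs of the agents' phenotypes; their product is the synergy
    score, with scores above 0.9 flagged as likely same-target action.
    Includes meet/min and GO Union-Intersection baselines, Bliss
    independence and maximum-increased-inhibition-rate analysis of
    dose-response tables, a permutation-robustness protocol over agent genes
    and network edges, and a synthetic-data generator with plantable
    synergistic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
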
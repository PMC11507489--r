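Package: edgecred
Title: Credible Intervals for Edges of Bayesian Networks Learned from Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assesses the credibility of the structure of Bayesian networks
    learned from discrete data. An ensemble of networks is learned from
    bootstrap replicates of the dataset by score-based hill climbing
    (BIC or BDeu); for every pair of variables the three edge states
    (left-directed, absent, right-directed) observed across the ensemble
    are modelled with a conjugate Dirichlet-Multinomial posterior, giving
    posterior means, equal-tailed credible intervals, edge existence and
    direction probabilities, and a thresholded maximum a posteriori graph.
    Includes a discrete Bayesian-network simulator (ancestral sampling,
    CPT fitting, exact inference by variable elimination) used to generate
    synthetic benchmarks and to evaluate inference accuracy, plus a
    Beta-Binomial per-arc baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
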
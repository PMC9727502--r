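Package: cognigeo
Title: Cognitive Geometry of Information-Bounded Agents in Gridworld MDPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves cost-only tabular Markov decision processes on empty
    rectangular gridworlds for free-energy-optimal policies under a
    decision-information cost with a live-distribution action prior, using a
    double Bellman/Blahut-Arimoto iteration. Derives the induced cognitive
    geometry: all-pairs free-energy distance matrices, symmetrization,
    stress-minimizing multidimensional-scaling embeddings, and exhaustive
    quasi-metric audits. Searches for value geodesics and epsilon-infodesics,
    chains per-segment optimal subgoal policies, builds interim-state
    histograms, and samples trajectories. Includes a command-line front end
    with TSV/JSON artifact output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan,
    withr
Config/testthat/edition: 3
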
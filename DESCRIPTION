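Package: foldprm
Title: Probabilistic Roadmaps for Protein Folding with Adaptive Neighbor
    Connection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds roadmap models of protein folding landscapes over a
    coarse-grained phi/psi torsional chain. Conformations are sampled by
    iterative native-biased perturbation with an energy-ramp acceptance
    rule, connected to nearest neighbours by straight-line torsional
    interpolation with Boltzmann edge weights, and folding pathways are
    extracted as minimum-weight paths from unfolded states to the native
    state. The connection phase can be driven by an Exp3-style
    multi-armed bandit (Adaptive Neighbor Connection) that selects among
    candidate connection methods using either run-wide performance
    history or history replayed from the local neighbourhood of each
    query conformation, as well as by fixed single-metric baselines.
    Includes secondary-structure formation-order analysis, pathway
    quality metrics, synthetic toy-protein generators and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
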
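Package: phyloscape
Title: Tree Landscapes: Robinson-Foulds Distances, Nonlinear
    Dimensionality Reduction and Convex-Hull Summaries for Sets of
    Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Visualizes "tree landscapes": large collections of
    phylogenetic trees (for example bootstrap trees from many gene
    partitions) embedded in 2 or 3 dimensions so that Euclidean
    distances between points approximate Robinson-Foulds distances
    between trees.  Provides a Robinson-Foulds distance matrix over
    Newick tree sets, four nonlinear dimensionality-reduction stress
    functions (normalized, Kruskal-1, Sammon/NLM, curvilinear
    components analysis) with five optimizers (SMACOF majorization,
    Gauss-Seidel-Newton, stochastic gradient descent, MCMC simulated
    annealing, fixed-step linear iteration) and the 14 admissible
    pairings, intrinsic-dimensionality estimators (correlation
    dimension, maximum-likelihood, nearest-neighbor, stress-versus-
    dimension curves), embedding diagnostics (1-nearest-neighbor label
    agreement, trustworthiness, continuity, ordinary Procrustes
    comparison of replicate runs), and convex-hull cluster summaries
    with variance-threshold outlier pruning and parallel hull
    separation.  Includes seeded generators for synthetic tree
    landscapes and manifold samples so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
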
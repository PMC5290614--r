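#' Uniform random unrooted binary tree topology
#'
#' Builds a tree by sequential random leaf attachment: starting from the
#' unique 3-leaf star, each new leaf is attached to an edge chosen
#' uniformly among the current edges.  Every unrooted binary topology on n
#' labelled leaves arises from exactly one attachment history, so the
#' draw is uniform over the (2n-5)!! topologies.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param seed Integer seed; same seed, same tree.
#' @param tip_labels Optional character vector of leaf names (default
#'   `t01`, `t02`, ...).
#' @return A `phylo` object (no branch lengths).
#' @export
random_tree <- function(n_taxa, seed = NULL, tip_labels = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 4L) stop("need at least 4 taxa", call. = FALSE)
  if (is.null(tip_labels)) {
    tip_labels <- sprintf("t%0*d", nchar(n_taxa), seq_len(n_taxa))
  }
  stopifnot(length(tip_labels) == n_taxa)
  with_seed(seed, {
    # edges as parent/child vectors; tips 1..n, internal nodes from n+1
    root <- n_taxa + 1L
    parent <- rep(root, 3L)
    child <- 1:3
    next_node <- root + 1L
    for (leaf in seq_len(n_taxa)[-(1:3)]) {
      e <- sample.int(length(parent), 1L)
      u <- parent[e]; v <- child[e]
      w <- next_node; next_node <- next_node + 1L
      parent[e] <- u; child[e] <- w        # u -> w
      parent <- c(parent, w, w)
      child <- c(child, v, leaf)           # w -> v, w -> leaf
    }
    # serialize to Newick from the adjacency (parent orientation)
    kids <- split(child, parent)
    dfs <- function(v) {
      if (v <= n_taxa) return(tip_labels[v])
      paste0("(", paste(vapply(kids[[as.character(v)]], dfs, character(1)),
                        collapse = ","), ")")
    }
    ape::read.tree(text = paste0(dfs(root), ";"))
  })
}

#' Simulate a clustered tree landscape
#'
#' Generates the statistical structure a multi-gene bootstrap study
#' exhibits: K partitions, each contributing a cluster of topologically
#' similar trees whose within-cluster spread shrinks as the partition
#' grows.  Each member tree is produced by applying a Poisson number of
#' random nearest-neighbor-interchange (NNI) moves to its partition's
#' center tree, with expected move count `rate_scale / length` — shorter
#' partitions carry fewer informative characters, so their bootstrap
#' trees scatter more widely.
#'
#' Two modes: `"clustered"` gives each partition its own independent
#' random center topology (distinct clusters, the typical real-data
#' shape); `"null"` shares a single center across all partitions,
#' emulating partitions that differ only by sampling error, so within-
#' and between-partition distances match in distribution.
#'
#' The bootstrap machinery itself (resampling alignment columns, ML tree
#' search) is not simulated; the NNI cluster model reproduces only the
#' distributional shape the landscape methods consume.
#'
#' @param n_taxa Number of leaves (>= 8 for non-trivial landscapes).
#' @param lengths Numeric vector, one "partition length" (alignment-size
#'   proxy, e.g. base pairs) per partition.  Default: 5 partitions from
#'   200 to 1800, spanning short to long mitochondrial genes.
#' @param n_trees Trees per partition (single value recycled; default
#'   100, one per bootstrap replicate).
#' @param labels Partition labels (default `part01`...).
#' @param mode `"clustered"` or `"null"`.
#' @param rate_scale Numerator of the NNI rate `rate_scale / length`
#'   (default 2000: a 200-site partition averages 10 moves, an 1800-site
#'   one about one move).
#' @param base_seed Integer seed; the whole landscape is reproducible
#'   from it.
#' @return A `"treeset"`, with attribute `"lengths"` (named per
#'   partition) for downstream trend checks.
#' @export
simulate_landscape <- function(n_taxa = 20L,
                               lengths = seq(200, 1800, length.out = 5),
                               n_trees = 100L, labels = NULL,
                               mode = c("clustered", "null"),
                               rate_scale = 2000, base_seed = 1L) {
  mode <- match.arg(mode)
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 8L) stop("need at least 8 taxa", call. = FALSE)
  if (any(lengths <= 0)) stop("partition lengths must be positive",
                              call. = FALSE)
  K <- length(lengths)
  n_trees <- rep(as.integer(n_trees), length.out = K)
  if (any(n_trees < 2L)) stop("need at least 2 trees per partition",
                              call. = FALSE)
  if (is.null(labels)) labels <- sprintf("part%02d", seq_len(K))
  stopifnot(length(labels) == K)
  centers <- if (mode == "null") {
    rep(list(random_tree(n_taxa, seed = derive_seed(base_seed, 0L))), K)
  } else {
    lapply(seq_len(K), function(g) {
      random_tree(n_taxa, seed = derive_seed(base_seed, g))
    })
  }
  trees <- list()
  partition <- character(0)
  for (g in seq_len(K)) {
    rate <- rate_scale / lengths[g]
    trees_g <- with_seed(derive_seed(base_seed, 1000L + g), {
      lapply(seq_len(n_trees[g]), function(i) {
        moves <- stats::rpois(1L, rate)
        if (moves > 0L) phangorn::rNNI(centers[[g]], moves = moves, n = 1L)
        else centers[[g]]
      })
    })
    trees <- c(trees, trees_g)
    partition <- c(partition, rep(labels[g], n_trees[g]))
  }
  ts <- new_treeset(trees, partition)
  attr(ts, "lengths") <- stats::setNames(lengths, labels)
  ts
}

#' Sample points from a named manifold, with their distance matrix
#'
#' Seeded test-bed generator for the intrinsic-dimensionality estimators:
#' draws n i.i.d. points from a manifold of known dimension at unit scale
#' and returns both the coordinates (ground truth) and the Euclidean
#' distance matrix.
#'
#' @param kind One of `"segment"` (d = 1), `"square"` (d = 2), `"cube"`
#'   (d = 3), `"gaussian_d"` (d = `d`), `"swiss_roll"` (2-manifold rolled
#'   into 3-space).
#' @param n Number of points (>= 10).
#' @param d Dimension for `"gaussian_d"` (ignored otherwise).
#' @param seed Integer seed.
#' @param ambient If given, embed the sample into this many ambient
#'   dimensions by a seeded random rotation (distances unchanged).
#' @return List with `points` (n x p matrix) and `dist` (an `"rf_dist"`
#'   container with `metric_name = "euclidean"`).
#' @export
sample_manifold <- function(kind = c("segment", "square", "cube",
                                     "gaussian_d", "swiss_roll"),
                            n = 1000L, d = 2L, seed = 1L, ambient = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 10L) stop("need at least 10 points", call. = FALSE)
  pts <- with_seed(seed, switch(kind,
    segment = matrix(stats::runif(n), ncol = 1L),
    square = matrix(stats::runif(2L * n), ncol = 2L),
    cube = matrix(stats::runif(3L * n), ncol = 3L),
    gaussian_d = matrix(stats::rnorm(n * d), ncol = d),
    swiss_roll = {
      t <- stats::runif(n, 1.5 * pi, 4.5 * pi)
      h <- stats::runif(n)
      cbind(t * cos(t), h, t * sin(t)) / (4.5 * pi)
    }
  ))
  if (!is.null(ambient)) {
    p <- ncol(pts)
    if (ambient < p) stop("`ambient` must be at least the manifold's own ",
                          "embedding dimension", call. = FALSE)
    Q <- with_seed(derive_seed(seed, 77L),
                   qr.Q(qr(matrix(stats::rnorm(ambient * ambient), ambient))))
    pts <- cbind(pts, matrix(0, n, ambient - p)) %*% Q
  }
  list(points = pts,
       dist = new_rf_dist(embedded_distances(pts),
                          metric_name = "euclidean"))
}
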
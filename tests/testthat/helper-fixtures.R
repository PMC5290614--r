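# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files.

tree_of <- function(txt) ape::read.tree(text = txt)

# Distance matrix that is exactly embeddable in p dimensions.
embeddable_delta <- function(n, p = 2, seed = 7) {
  pts <- phyloscape:::with_seed(seed, matrix(stats::runif(n * p), n, p))
  list(points = pts, delta = as.matrix(stats::dist(pts)))
}

# Tiny treeset built from explicit Newick strings.
treeset_of <- function(txts, partition = NULL) {
  trees <- lapply(txts, tree_of)
  if (is.null(partition)) partition <- rep("p1", length(trees))
  phyloscape:::new_treeset(trees, partition)
}

# Write Newick strings to a temp file, one tree per line.
write_newick_tmp <- function(txts) {
  path <- tempfile(fileext = ".nwk")
  writeLines(txts, path)
  path
}

# Independent split-set RF oracle: sorted strings of sorted leaf-name
# sides, smallest side first (ties by name) -- no bitmasks, no shared code
# with the package implementation.
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  edge <- tree$edge
  out <- character(0)
  for (node in unique(edge[edge[, 2] > n, 2])) {
    below <- sort(ape::extract.clade(tree, node)$tip.label)
    if (length(below) < 2 || length(below) > n - 2) next
    other <- sort(setdiff(tips, below))
    sides <- sort(c(paste(below, collapse = ","),
                    paste(other, collapse = ",")))
    out <- c(out, paste(sides, collapse = "|"))
  }
  unique(out)
}

oracle_rf <- function(a, b) {
  sa <- oracle_splits(a)
  sb <- oracle_splits(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}
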
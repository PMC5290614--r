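#' Read a set of trees from one or more Newick files
#'
#' Concatenates the trees found in `paths`, in file order, into a single
#' labelled tree set.  Each file is treated as one data partition (for
#' example, the bootstrap trees of one gene); the partition label defaults
#' to the file name without its extension.  All trees must share one leaf
#' label set: tree landscapes compare topologies on identical taxa, so a
#' mismatch is an input error, reported with the offending labels.
#'
#' Trees are handled as unrooted topologies throughout: rooted Newick input
#' is accepted and unrooted internally, and branch lengths are parsed but
#' ignored downstream (the Robinson-Foulds distance is topology-only).
#'
#' @param paths Character vector of Newick file paths.  Each file may
#'   contain one or more semicolon-terminated trees.
#' @param labels Optional character vector of partition labels, one per
#'   file, overriding the file-name default.
#' @param labels_file Optional path to a TSV with columns `tree_index`
#'   (0-based, over the concatenated set) and `partition_label`, overriding
#'   per-tree labels after concatenation.
#' @return An object of class `"treeset"`: a list with `trees` (a
#'   `multiPhylo`), `leaf_labels` (sorted taxon names), `partition`
#'   (character, one label per tree) and `source_files`.
#' @seealso [write_treeset()], [rf_matrix()], [simulate_landscape()]
#' @export
read_treeset <- function(paths, labels = NULL, labels_file = NULL) {
  if (length(paths) < 1L) stop("no input files given", call. = FALSE)
  if (!is.null(labels) && length(labels) != length(paths)) {
    stop("`labels` must have one entry per file", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- sub("\\.[^.]*$", "", basename(paths))
  }
  trees <- list()
  partition <- character(0)
  for (f in seq_along(paths)) {
    path <- paths[[f]]
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    pieces <- strsplit(txt, ";", fixed = TRUE)[[1]]
    pieces <- pieces[nzchar(trimws(pieces))]
    if (length(pieces) == 0L) {
      stop(sprintf("no trees found in %s", path), call. = FALSE)
    }
    for (k in seq_along(pieces)) {
      tr <- tryCatch(
        ape::read.tree(text = paste0(trimws(pieces[[k]]), ";")),
        error = function(e) NULL
      )
      if (is.null(tr) || !inherits(tr, "phylo")) {
        stop(sprintf("malformed Newick in %s, tree %d", path, k), call. = FALSE)
      }
      trees[[length(trees) + 1L]] <- tr
      partition <- c(partition, labels[[f]])
    }
  }
  ts <- new_treeset(trees, partition, source_files = paths)
  if (!is.null(labels_file)) {
    lab <- read_partition_labels(labels_file)
    idx <- lab$tree_index + 1L
    if (any(idx < 1L | idx > length(ts$trees))) {
      stop("labels file indexes trees outside the set", call. = FALSE)
    }
    ts$partition[idx] <- lab$partition_label
  }
  ts
}

# Construct and validate a treeset from a list of phylo objects.
new_treeset <- function(trees, partition, source_files = character(0)) {
  if (length(trees) < 1L) stop("a treeset needs at least one tree", call. = FALSE)
  if (length(partition) != length(trees)) {
    stop("one partition label per tree is required", call. = FALSE)
  }
  leaf_labels <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    li <- sort(trees[[i]]$tip.label)
    if (!identical(li, leaf_labels)) {
      only_first <- setdiff(leaf_labels, li)
      only_this <- setdiff(li, leaf_labels)
      stop(sprintf(
        "leaf sets differ: tree %d lacks {%s} and adds {%s}",
        i, paste(only_first, collapse = ", "), paste(only_this, collapse = ", ")
      ), call. = FALSE)
    }
  }
  trees <- lapply(trees, function(tr) {
    tr <- ape::unroot(tr)
    tr$node.label <- NULL  # support values ignored
    tr
  })
  class(trees) <- "multiPhylo"
  structure(
    list(
      trees = trees,
      leaf_labels = leaf_labels,
      partition = as.character(partition),
      source_files = source_files
    ),
    class = "treeset"
  )
}

#' @export
print.treeset <- function(x, ...) {
  cat(sprintf(
    "treeset: %d trees on %d taxa, %d partition(s)\n",
    length(x$trees), length(x$leaf_labels), length(unique(x$partition))
  ))
  tab <- table(x$partition)
  for (g in names(tab)) cat(sprintf("  %s: %d trees\n", g, tab[[g]]))
  invisible(x)
}

#' @export
length.treeset <- function(x) length(x$trees)

#' Write a tree set to disk
#'
#' Writes all trees to one Newick file and the per-tree partition labels to
#' a TSV with columns `tree_index` (0-based) and `partition_label`, the
#' same format [read_treeset()] accepts via `labels_file`.
#'
#' @param ts A `"treeset"`.
#' @param tree_file Output Newick path.
#' @param labels_file Output TSV path (default: `tree_file` with a
#'   `.labels.tsv` suffix).
#' @return Invisibly, the two paths written.
#' @export
write_treeset <- function(ts, tree_file,
                          labels_file = paste0(tree_file, ".labels.tsv")) {
  stopifnot(inherits(ts, "treeset"))
  ape::write.tree(ts$trees, file = tree_file)
  utils::write.table(
    data.frame(
      tree_index = seq_along(ts$trees) - 1L,
      partition_label = ts$partition
    ),
    labels_file, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(tree_file, labels_file))
}

#' Read a partition-label table
#'
#' @param path TSV with columns `tree_index` (0-based) and
#'   `partition_label`.
#' @return A data frame with those two columns.
#' @export
read_partition_labels <- function(path) {
  lab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("tree_index", "partition_label")
  if (!all(need %in% names(lab))) {
    stop("labels file must have columns tree_index and partition_label",
         call. = FALSE)
  }
  lab$tree_index <- as.integer(lab$tree_index)
  lab$partition_label <- as.character(lab$partition_label)
  lab
}

#' Non-trivial bipartitions (splits) of an unrooted tree
#'
#' Every internal edge of an unrooted tree cuts the leaves into two sets; a
#' split is non-trivial when both sides have at least two leaves.  A fully
#' resolved unrooted tree on n leaves has n - 3 such splits; polytomies
#' yield fewer.  Splits are returned in a canonical encoding — a 0/1
#' membership string over `leaf_order`, complemented so the first leaf is
#' always on the `0` side — making split-set comparisons exact string
#' comparisons, independent of rooting and of child ordering in the Newick
#' source.
#'
#' @param tree A `phylo` object (rooted input is unrooted internally).
#' @param leaf_order Character vector fixing the leaf ordering of the
#'   encoding; defaults to `sort(tree$tip.label)`.  Distance computations
#'   across trees must share one ordering.
#' @return Object of class `"bipartitions"`: list with `splits` (character
#'   vector, canonical encodings, no duplicates) and `n_leaves`.
#' @examples
#' tr <- ape::read.tree(text = "(((A,B),C),(D,E));")
#' bipartitions(tr)$splits  # two splits: AB|CDE and ABC|DE
#' @export
bipartitions <- function(tree, leaf_order = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 4L) {
    stop("trees with fewer than 4 leaves have no non-trivial splits",
         call. = FALSE)
  }
  if (is.null(leaf_order)) leaf_order <- sort(tree$tip.label)
  if (!setequal(leaf_order, tree$tip.label) || length(leaf_order) != n) {
    stop("`leaf_order` must be a permutation of the tree's tip labels",
         call. = FALSE)
  }
  tree <- ape::unroot(tree)
  edge <- tree$edge
  n_node <- tree$Nnode
  # membership of each tip in the canonical ordering
  tip_pos <- match(tree$tip.label, leaf_order)
  # post-order accumulation of the tip set below each node
  below <- matrix(FALSE, nrow = n + n_node, ncol = n)
  below[cbind(seq_len(n), tip_pos)] <- TRUE
  for (e in ape::postorder(tree)) {
    parent <- edge[e, 1L]
    child <- edge[e, 2L]
    below[parent, ] <- below[parent, ] | below[child, ]
  }
  # one split per internal edge = per edge whose child is an internal node
  internal_children <- edge[edge[, 2L] > n, 2L]
  splits <- character(0)
  for (v in internal_children) {
    side <- below[v, ]
    k <- sum(side)
    if (k < 2L || k > n - 2L) next
    if (side[1L]) side <- !side
    splits <- c(splits, paste(as.integer(side), collapse = ""))
  }
  structure(
    list(splits = unique(splits), n_leaves = n, leaf_order = leaf_order),
    class = "bipartitions"
  )
}

#' @export
print.bipartitions <- function(x, ...) {
  cat(sprintf("%d non-trivial split(s) on %d leaves\n",
              length(x$splits), x$n_leaves))
  invisible(x)
}
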
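#' Robinson-Foulds distance between two trees
#'
#' The RF distance counts the bipartitions (splits) present in one but not
#' both trees: the size of the symmetric difference of their non-trivial
#' split sets.  Both trees are treated as unrooted; branch lengths play no
#' role.  For two fully resolved trees on n leaves the distance is an even
#' integer between 0 and 2(n - 3).
#'
#' @param tree_a,tree_b `phylo` objects on the same leaf set.
#' @param normalize If `TRUE`, divide by the maximum 2(n - 3).
#' @return A single nonnegative number (an integer unless normalized).
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D));")
#' t2 <- ape::read.tree(text = "((A,C),(B,D));")
#' rf(t1, t2)  # 2
#' @export
rf <- function(tree_a, tree_b, normalize = FALSE) {
  la <- sort(tree_a$tip.label)
  lb <- sort(tree_b$tip.label)
  if (!identical(la, lb)) {
    stop(sprintf(
      "leaf sets differ: only in first {%s}, only in second {%s}",
      paste(setdiff(la, lb), collapse = ", "),
      paste(setdiff(lb, la), collapse = ", ")
    ), call. = FALSE)
  }
  sa <- bipartitions(tree_a, leaf_order = la)$splits
  sb <- bipartitions(tree_b, leaf_order = la)$splits
  d <- length(sa) + length(sb) - 2L * sum(sa %in% sb)
  if (normalize) d / (2 * (length(la) - 3)) else as.numeric(d)
}

#' Robinson-Foulds distance matrix over a tree set
#'
#' Computes all pairwise RF distances among the trees of a tree set,
#' yielding the dissimilarity matrix that all downstream landscape analyses
#' (embedding, dimensionality estimation, diagnostics) consume.  Duplicate
#' topologies are retained and give zero off-diagonal entries.
#'
#' Splits are pooled across trees into one dictionary so each tree becomes
#' a row of a tree-by-split incidence matrix; shared-split counts for all
#' pairs are then a single cross-product, which keeps the computation
#' practical for thousands of trees.
#'
#' @param ts A `"treeset"` from [read_treeset()] or
#'   [simulate_landscape()], with at least two trees.
#' @param normalize If `TRUE`, distances divided by 2(n_leaves - 3).
#' @return Object of class `"rf_dist"`: list with `delta` (N x N symmetric
#'   numeric matrix), `labels` (partition label per row) and `metric_name`.
#' @export
rf_matrix <- function(ts, normalize = FALSE) {
  stopifnot(inherits(ts, "treeset"))
  n_tree <- length(ts$trees)
  if (n_tree < 2L) stop("need at least two trees", call. = FALSE)
  leaf_order <- ts$leaf_labels
  split_sets <- lapply(ts$trees, function(tr) {
    bipartitions(tr, leaf_order = leaf_order)$splits
  })
  dict <- unique(unlist(split_sets, use.names = FALSE))
  sizes <- vapply(split_sets, length, integer(1))
  inc <- matrix(0, nrow = n_tree, ncol = length(dict))
  for (i in seq_len(n_tree)) {
    inc[i, match(split_sets[[i]], dict)] <- 1
  }
  shared <- tcrossprod(inc)
  delta <- outer(sizes, sizes, `+`) - 2 * shared
  delta[delta < 0] <- 0  # numerical safety; exact arithmetic keeps it >= 0
  diag(delta) <- 0
  if (normalize) delta <- delta / (2 * (length(leaf_order) - 3))
  new_rf_dist(delta, labels = ts$partition,
              metric_name = if (normalize) "RF/max" else "RF")
}

new_rf_dist <- function(delta, labels = NULL, metric_name = "RF") {
  delta <- as_delta_matrix(delta)
  n <- nrow(delta)
  if (is.null(labels)) labels <- rep("all", n)
  if (length(labels) != n) stop("one label per row required", call. = FALSE)
  structure(
    list(delta = delta, labels = as.character(labels),
         metric_name = metric_name),
    class = "rf_dist"
  )
}

#' @export
print.rf_dist <- function(x, ...) {
  off <- x$delta[upper.tri(x$delta)]
  cat(sprintf(
    "%s distance matrix: %d x %d, mean off-diagonal %.3f, max %.3f\n",
    x$metric_name, nrow(x$delta), ncol(x$delta), mean(off), max(off)
  ))
  invisible(x)
}

#' Write a distance matrix
#'
#' Two plain-text formats are supported: a full square CSV with a header
#' row of tree ids, and the PHYLIP-style lower-triangular whitespace format
#' (first line N, then one row per point: id followed by the distances to
#' all earlier points).
#'
#' @param dm An `"rf_dist"` (or plain symmetric matrix).
#' @param path Output path.
#' @param format `"csv"` (square) or `"phylip"` (lower-triangular).
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  delta <- as_delta_matrix(dm)
  n <- nrow(delta)
  ids <- paste0("t", seq_len(n) - 1L)
  if (format == "csv") {
    df <- as.data.frame(delta)
    names(df) <- ids
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(n), con)
    for (i in seq_len(n)) {
      row <- if (i == 1L) ids[1L] else {
        paste(c(ids[i], format(delta[i, seq_len(i - 1L)], trim = TRUE)),
              collapse = " ")
      }
      writeLines(row, con)
    }
  }
  invisible(path)
}

#' Read a distance matrix, auto-detecting its format
#'
#' Accepts the square CSV and PHYLIP-style lower-triangular formats
#' written by [write_distance_matrix()]; the format is detected from the
#' row lengths.  Any externally computed tree-to-tree metric can enter the
#' pipeline this way.
#'
#' @param path Input path.
#' @param labels Optional partition labels (recycled errors are not
#'   allowed; one per row).
#' @return An `"rf_dist"` object (with `metric_name` `"file"`).
#' @export
read_distance_matrix <- function(path, labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("distance file too short", call. = FALSE)
  first_fields <- strsplit(trimws(lines[[1]]), "[,[:space:]]+")[[1]]
  is_phylip <- length(first_fields) == 1L &&
    !is.na(suppressWarnings(as.integer(first_fields[[1]])))
  if (is_phylip) {
    n <- as.integer(first_fields[[1]])
    if (length(lines) != n + 1L) {
      stop("lower-triangular file: row count does not match header N",
           call. = FALSE)
    }
    delta <- matrix(0, n, n)
    for (i in seq_len(n)) {
      fields <- strsplit(trimws(lines[[i + 1L]]), "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields[-1L]))
      if (length(vals) != i - 1L || any(is.na(vals))) {
        stop(sprintf("lower-triangular row %d malformed", i), call. = FALSE)
      }
      if (i > 1L) {
        delta[i, seq_len(i - 1L)] <- vals
        delta[seq_len(i - 1L), i] <- vals
      }
    }
  } else {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    delta <- as.matrix(df)
    if (nrow(delta) != ncol(delta)) {
      stop("square CSV must have N rows and N columns", call. = FALSE)
    }
  }
  new_rf_dist(delta, labels = labels, metric_name = "file")
}
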
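# Rank matrix of a distance matrix: rank[i, j] = position of j in i's
# ordering by distance, ties broken by index; 0 on the diagonal.
rank_matrix <- function(dmat) {
  n <- nrow(dmat)
  rnk <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    o <- others[order(dmat[i, others], others)]
    rnk[i, o] <- seq_len(n - 1L)
  }
  rnk
}

# Core of trustworthiness/continuity: penalize points that are among i's k
# nearest by `near` ranks but not by `far` ranks, weighted by their `far`
# rank excess over k.
rank_penalty_score <- function(rank_near, rank_far, k) {
  n <- nrow(rank_near)
  if (!(k >= 1L && k < n / 2)) {
    stop("need 1 <= k < N/2", call. = FALSE)
  }
  total <- 0
  for (i in seq_len(n)) {
    intruders <- which(rank_near[i, ] <= k & rank_far[i, ] > k)
    total <- total + sum(rank_far[i, intruders] - k)
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}

#' Trustworthiness of an embedding
#'
#' Penalizes spurious neighbors: points that appear among i's k nearest in
#' the embedding but are not among its k nearest by the original
#' dissimilarities, weighted by how far down the original ordering they
#' really sit:
#' \deqn{T(k) = 1 - \frac{2}{Nk(2N - 3k - 1)} \sum_i
#'   \sum_{j \in U_k(i)} (r(i, j) - k),}
#' where \eqn{U_k(i)} holds the intruders and \eqn{r(i,j)} is j's rank in
#' i's ordering by \eqn{\delta}.  Equals 1 for any embedding whose
#' distance ranks match the original ranks.  Rank ties (frequent with
#' integer RF distances) are broken by point index.
#'
#' @param delta Original dissimilarity matrix or `"rf_dist"`.
#' @param X N x p embedding coordinates (or an `"embedding"`).
#' @param k Neighborhood size, `1 <= k < N/2`.
#' @return Scalar in `[0, 1]`.
#' @export
trustworthiness <- function(delta, X, k = 5L) {
  delta <- as_delta_matrix(delta)
  if (inherits(X, "embedding")) X <- X$X
  d_emb <- embedded_distances(X)
  rank_penalty_score(rank_matrix(d_emb), rank_matrix(delta), as.integer(k))
}

#' Continuity of an embedding
#'
#' The mirror image of [trustworthiness()]: penalizes true neighbors lost
#' by the embedding — points among i's k nearest by the original
#' dissimilarities but not among its k nearest in the embedding — with
#' ranks taken in embedding space.  A projection that tears a cluster
#' apart loses continuity before it loses trustworthiness.
#'
#' @inheritParams trustworthiness
#' @return Scalar in `[0, 1]`.
#' @export
continuity <- function(delta, X, k = 5L) {
  delta <- as_delta_matrix(delta)
  if (inherits(X, "embedding")) X <- X$X
  d_emb <- embedded_distances(X)
  rank_penalty_score(rank_matrix(delta), rank_matrix(d_emb), as.integer(k))
}

#' Nearest-neighbor label agreement (1NN)
#'
#' Fraction of points whose nearest neighbor (self excluded, ties broken
#' by lowest index) carries the same partition label.  Computed on an
#' embedding it measures how well the projection keeps labelled clusters
#' of trees together; computed on the original distance matrix it gives
#' the ceiling the embedding is compared against.
#'
#' @param space Either an N x p coordinate matrix / `"embedding"` or an
#'   N x N distance matrix / `"rf_dist"`.
#' @param labels Partition label per point; at least two distinct labels.
#' @return Scalar in `[0, 1]`.
#' @export
one_nn <- function(space, labels) {
  if (inherits(space, "embedding")) space <- space$X
  if (inherits(space, "rf_dist")) {
    dmat <- space$delta
  } else {
    space <- as.matrix(space)
    is_dist <- nrow(space) == ncol(space) &&
      all(abs(space - t(space)) < 1e-12) && all(diag(space) == 0)
    dmat <- if (is_dist) space else embedded_distances(space)
  }
  n <- nrow(dmat)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per point required", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("1NN label agreement is degenerate with a single label", call. = FALSE)
  }
  hits <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    nn <- others[order(dmat[i, others], others)][1L]
    labels[nn] == labels[i]
  }, logical(1))
  mean(hits)
}

#' Embedding fit report
#'
#' @param delta Original dissimilarities.
#' @param X Embedding coordinates (or `"embedding"`).
#' @param labels Partition labels (needed for the 1NN statistic).
#' @param ks Neighborhood sizes for trustworthiness/continuity.
#' @return Object of class `"fit_report"`: `one_nn`, `one_nn_delta`
#'   (same statistic on the original distances), `trustworthiness` and
#'   `continuity` (named by k).
#' @export
fit_report <- function(delta, X, labels, ks = c(1L, 5L, 10L, 20L)) {
  delta <- as_delta_matrix(delta)
  if (inherits(X, "embedding")) X <- X$X
  ks <- ks[ks < nrow(delta) / 2]
  tw <- vapply(ks, function(k) trustworthiness(delta, X, k), numeric(1))
  ct <- vapply(ks, function(k) continuity(delta, X, k), numeric(1))
  names(tw) <- names(ct) <- paste0("k", ks)
  structure(
    list(one_nn = one_nn(X, labels),
         one_nn_delta = one_nn(new_rf_dist(delta), labels),
         trustworthiness = tw, continuity = ct, ks = ks),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("1NN label agreement: %.3f (on input distances: %.3f)\n",
              x$one_nn, x$one_nn_delta))
  for (i in seq_along(x$ks)) {
    cat(sprintf("  k=%d  trustworthiness %.3f  continuity %.3f\n",
                x$ks[i], x$trustworthiness[i], x$continuity[i]))
  }
  invisible(x)
}

#' Ordinary Procrustes superimposition
#'
#' Least-squares alignment of `X_other` onto `X_ref` over translation,
#' orthogonal transformation (rotations and reflections) and scale.  The
#' residual is the minimized sum of squared deviations divided by the
#' total sum of squares of the centered reference, so it lies in
#' `[0, 1]` and is 0 exactly when the two configurations are similar
#' shapes.
#'
#' @param X_ref,X_other N x p coordinate matrices (or `"embedding"`s) of
#'   identical shape.
#' @return Object of class `"procrustes_result"`: `residual`, `scale`,
#'   `rotation` (p x p orthogonal), `translation`, and `X_aligned`.
#' @export
procrustes <- function(X_ref, X_other) {
  if (inherits(X_ref, "embedding")) X_ref <- X_ref$X
  if (inherits(X_other, "embedding")) X_other <- X_other$X
  A <- as.matrix(X_ref); B <- as.matrix(X_other)
  if (!all(dim(A) == dim(B))) stop("configurations must have the same shape",
                                   call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  ssA <- sum(A0^2); ssB <- sum(B0^2)
  if (ssA == 0 || ssB == 0) {
    stop("degenerate configuration: all points coincident", call. = FALSE)
  }
  sv <- svd(crossprod(A0, B0))        # p x p; reflections allowed
  Q <- sv$v %*% t(sv$u)               # maps B0 onto A0: B0 %*% Q
  s <- sum(sv$d) / ssB
  fitted <- s * B0 %*% Q
  residual <- sum((A0 - fitted)^2) / ssA
  structure(
    list(residual = max(residual, 0), scale = s, rotation = Q,
         translation = ca - s * as.numeric(cb %*% Q),
         X_aligned = sweep(fitted, 2L, ca, `+`)),
    class = "procrustes_result"
  )
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes residual: %.6g (scale %.4g)\n", x$residual, x$scale))
  invisible(x)
}

#' Equivalence classes among replicate embeddings
#'
#' Replicate runs of a non-convex embedding from different initial
#' conditions may land in different local optima.  Two projections are
#' called non-equivalent when their Procrustes residual is very large
#' relative to the others; this is operationalized as: compute the
#' all-pairs residual matrix, flag a run whose median residual to the
#' other runs exceeds Q3 + 1.5 IQR of all pairwise residuals, and report
#' the unflagged majority as the equivalent group.
#'
#' @param batch A `"run_batch"`, or a list of embeddings / coordinate
#'   matrices (at least 2).
#' @return Object of class `"equivalence"`: `classes` (integer vector, 1 =
#'   majority group), `residuals` (symmetric matrix), `outliers` (indices).
#'   With exactly two runs the outlier rule is undefined and both runs are
#'   reported as one class with a warning.
#' @export
equivalence_classes <- function(batch) {
  runs <- if (inherits(batch, "run_batch")) batch$runs else batch
  Xs <- lapply(runs, function(r) if (inherits(r, "embedding")) r$X else
    as.matrix(r))
  nr <- length(Xs)
  if (nr < 2L) stop("need at least 2 runs", call. = FALSE)
  R <- matrix(0, nr, nr)
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      R[i, j] <- R[j, i] <- procrustes(Xs[[i]], Xs[[j]])$residual
    }
  }
  if (nr == 2L) {
    warning("outlier rule undefined with 2 runs; reporting one class")
    return(structure(list(classes = c(1L, 1L), residuals = R,
                          outliers = integer(0)),
                     class = "equivalence"))
  }
  offdiag <- R[upper.tri(R)]
  cut <- stats::quantile(offdiag, 0.75, names = FALSE) +
    1.5 * stats::IQR(offdiag)
  med <- vapply(seq_len(nr), function(i) stats::median(R[i, -i]), numeric(1))
  outliers <- which(med > cut)
  classes <- rep(1L, nr)
  if (length(outliers)) classes[outliers] <- 1L + seq_along(outliers)
  structure(list(classes = classes, residuals = R, outliers = outliers),
            class = "equivalence")
}

#' @export
print.equivalence <- function(x, ...) {
  cat(sprintf("%d run(s): majority class of %d, %d outlier(s)\n",
              length(x$classes), sum(x$classes == 1L), length(x$outliers)))
  invisible(x)
}
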
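# Variance of the pairwise Euclidean distances among points (the default
# spread measure for outlier pruning) or of distances to the centroid.
spread_variance <- function(points, centroid_based = FALSE) {
  if (centroid_based) {
    ctr <- colMeans(points)
    d <- sqrt(rowSums(sweep(points, 2L, ctr)^2))
  } else {
    d <- stats::dist(points)
  }
  if (length(d) < 2L) return(0)
  stats::var(as.numeric(d))
}

#' Variance-threshold outlier pruning
#'
#' A point is an outlier if the variance of the distances among all points
#' decreases by more than the threshold `tau` when the point is excluded
#' from the variance calculation.  Removal is greedy and iterative: at
#' each step the variance v of all pairwise distances among the current
#' points is computed, along with v_-q for each candidate q; if the
#' largest relative decrease (v - v_-q)/v exceeds `tau` the argmax point
#' is removed (ties broken by lowest index) and the step repeats.  The
#' default `tau = 0.01` removes only points whose presence dominates the
#' spread.  The threshold is read as a relative decrease so its meaning
#' does not depend on the coordinate scale; `absolute = TRUE` gives the
#' absolute reading.
#'
#' @param points N x p coordinate matrix, N >= 3.
#' @param tau Positive threshold (default 0.01).
#' @param absolute If `TRUE`, compare the raw decrease v - v_-q to `tau`.
#' @param centroid_based If `TRUE`, use the variance of distances to the
#'   centroid instead of all pairwise distances.
#' @return List with `retained` and `removed` (index vectors into the
#'   input) and `degenerate` (`TRUE` if pruning stopped because fewer than
#'   3 points would remain).
#' @export
prune_outliers <- function(points, tau = 0.01, absolute = FALSE,
                           centroid_based = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  stopifnot_scalar_number(tau, "tau", positive = TRUE)
  active <- seq_len(nrow(points))
  removed <- integer(0)
  degenerate <- FALSE
  repeat {
    if (length(active) < 3L) {
      degenerate <- TRUE
      break
    }
    v <- spread_variance(points[active, , drop = FALSE], centroid_based)
    if (v <= 0) break  # coincident or two-point spread: nothing to judge
    drops <- vapply(seq_along(active), function(qi) {
      v - spread_variance(points[active[-qi], , drop = FALSE], centroid_based)
    }, numeric(1))
    score <- if (absolute) drops else drops / v
    best <- which.max(score)  # which.max takes the lowest index on ties
    if (score[best] > tau) {
      removed <- c(removed, active[best])
      active <- active[-best]
    } else break
  }
  list(retained = active, removed = removed, degenerate = degenerate)
}

## ---- convex hulls ----------------------------------------------------------

# Affine rank of a point set (number of independent directions spanned).
affine_rank <- function(points, tol = 1e-9) {
  if (nrow(points) < 2L) return(0L)
  ctr <- sweep(points, 2L, colMeans(points))
  sv <- svd(ctr)$d
  sum(sv > tol * max(sv, 1))
}

# Incremental 3D convex hull returning triangular facets (indices into the
# input rows) with outward-oriented normals.  Input must have affine rank
# 3.  A deterministic symbolic-perturbation jitter resolves exactly
# coplanar exterior points (e.g. cube corners); facet vertex indices refer
# to the original coordinates.
hull3d <- function(points) {
  n <- nrow(points)
  scale <- max(apply(points, 2L, function(v) diff(range(v))))
  pts <- points + with_seed(8191L,
    matrix(stats::runif(n * 3L, -1, 1), n, 3L)) * scale * 1e-9
  # initial tetrahedron: spread points far apart
  i1 <- which.min(pts[, 1L])
  i2 <- which.max(rowSums(sweep(pts, 2L, pts[i1, ])^2))
  d12 <- pts[i2, ] - pts[i1, ]
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  line_d2 <- apply(pts, 1L, function(q) {
    w <- q - pts[i1, ]
    sum(cross3(w, d12)^2)
  })
  i3 <- which.max(line_d2)
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  plane_d <- abs(as.numeric((pts - matrix(pts[i1, ], n, 3L, byrow = TRUE)) %*% nrm))
  i4 <- which.max(plane_d)
  if (plane_d[i4] <= 1e-12 * max(scale^3, 1)) {
    stop("points are coplanar; no 3D hull", call. = FALSE)
  }
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  centroid0 <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nn * (centroid0 - pts[f[1], ])) > 0) f[c(1L, 3L, 2L)] else f
  }
  faces <- lapply(faces, orient)
  face_normal <- function(f) {
    nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    nn / sqrt(sum(nn^2))
  }
  eps <- 1e-12 * max(scale, 1)
  for (q in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- vapply(faces, function(f) {
      sum(face_normal(f) * (pts[q, ] - pts[f[1], ])) > eps
    }, logical(1))
    if (!any(vis)) next
    # horizon = edges shared by one visible and one hidden face
    edge_key <- function(a, b) paste(min(a, b), max(a, b))
    counts <- new.env(parent = emptyenv())
    for (f in faces[vis]) {
      for (e in list(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])) {
        k <- edge_key(e[1], e[2])
        prev <- if (is.null(counts[[k]])) NULL else counts[[k]]
        counts[[k]] <- if (is.null(prev)) list(1L, e) else
          list(prev[[1L]] + 1L, e)
      }
    }
    horizon <- list()
    for (k in ls(counts)) {
      if (counts[[k]][[1L]] == 1L) horizon[[length(horizon) + 1L]] <-
          counts[[k]][[2L]]
    }
    faces <- faces[!vis]
    inner <- Reduce(`+`, lapply(faces, function(f) colMeans(pts[f, ]))) /
      length(faces)
    for (e in horizon) {
      f <- c(e[1], e[2], q)
      nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
      if (sum(nn * (inner - pts[f[1], ])) > 0) f <- f[c(1L, 3L, 2L)]
      faces[[length(faces) + 1L]] <- f
    }
  }
  do.call(rbind, faces)
}

#' Convex hull of a point set in 2 or 3 dimensions
#'
#' Returns the hull facets of the points: ordered vertex indices of the
#' hull polygon in 2D, triangular facets (rows of vertex indices) in 3D.
#' Degenerate sets — collinear points in 2D, coplanar or collinear points
#' in 3D, or fewer than 3 points — fall back to a lower-dimensional hull
#' and are flagged as such (a segment is reported by its two extreme
#' points; a planar set in 3D by its polygon in the best-fit plane).
#'
#' @param points N x p coordinate matrix, p in `{2, 3}`.
#' @return Object of class `"convex_hull"`: list with `vertices` (indices
#'   of hull vertices), `facets` (2D: integer vector, polygon order; 3D:
#'   matrix of triangles), `dim` (intrinsic dimension of the hull) and
#'   `degenerate` flag.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  p <- ncol(points)
  if (!p %in% c(2L, 3L)) stop("hulls are computed in 2 or 3 dimensions",
                              call. = FALSE)
  n <- nrow(points)
  rank <- affine_rank(points)
  if (n < 3L || rank <= 1L) {
    # point or segment
    if (rank == 0L || n == 1L) {
      return(structure(list(vertices = 1L, facets = NULL, dim = 0L,
                            degenerate = TRUE), class = "convex_hull"))
    }
    dir <- points[which.max(rowSums(sweep(points, 2L, points[1L, ])^2)), ] -
      points[1L, ]
    proj <- as.numeric(sweep(points, 2L, points[1L, ]) %*% dir)
    v <- c(which.min(proj), which.max(proj))
    return(structure(list(vertices = unique(v), facets = NULL, dim = 1L,
                          degenerate = TRUE), class = "convex_hull"))
  }
  if (p == 2L || rank == 2L) {
    if (p == 3L) {
      # project onto the best-fit plane
      ctr <- sweep(points, 2L, colMeans(points))
      basis <- svd(ctr)$v[, 1:2, drop = FALSE]
      pts2 <- ctr %*% basis
    } else pts2 <- points
    ord <- grDevices::chull(pts2[, 1L], pts2[, 2L])
    return(structure(
      list(vertices = sort(unique(ord)), facets = as.integer(ord), dim = 2L,
           degenerate = p == 3L),
      class = "convex_hull"
    ))
  }
  facets <- hull3d(points)
  structure(
    list(vertices = sort(unique(as.integer(facets))), facets = facets,
         dim = 3L, degenerate = FALSE),
    class = "convex_hull"
  )
}

#' @export
print.convex_hull <- function(x, ...) {
  nf <- if (is.null(x$facets)) 0L else
    if (is.matrix(x$facets)) nrow(x$facets) else length(x$facets)
  cat(sprintf("convex hull: %d vertices, %d facet entries, dim %d%s\n",
              length(x$vertices), nf, x$dim,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Per-partition convex-hull summary of an embedded tree landscape
#'
#' For each partition label: prune outlying trees by the variance
#' threshold, compute the convex hull of the retained points, and record
#' the group centroid.  The result can then be drawn, compared across
#' landscapes via the centroid configuration, or spread apart with
#' [separate_hulls()] to reveal hulls hiding near the origin.
#'
#' @param X N x p embedding coordinates (or an `"embedding"`), p in 2..3.
#' @param labels Partition label per point.
#' @param tau Outlier-pruning threshold (see [prune_outliers()]).
#' @param ... Passed to [prune_outliers()].
#' @return Object of class `"hull_summary"`: list with `groups` (named
#'   list per partition: `points` — the group's coordinates after any
#'   translation, `index` — row indices into X, `retained`, `removed` —
#'   indices into X, `hull`, `centroid`), `global_centroid`, `tau`,
#'   `separation` (cumulative factor applied by [separate_hulls()]) and
#'   `p`.
#' @export
hull_summary <- function(X, labels, tau = 0.01, ...) {
  if (inherits(X, "embedding")) X <- X$X
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("one label per point required",
                                      call. = FALSE)
  groups <- list()
  for (g in unique(labels)) {
    idx <- which(labels == g)
    pts <- X[idx, , drop = FALSE]
    pr <- if (length(idx) >= 3L) prune_outliers(pts, tau = tau, ...) else
      list(retained = seq_along(idx), removed = integer(0), degenerate = TRUE)
    kept <- pts[pr$retained, , drop = FALSE]
    hull <- if (nrow(kept) >= 1L) convex_hull(kept) else NULL
    groups[[g]] <- list(
      points = kept,
      index = idx,
      retained = idx[pr$retained],
      removed = idx[pr$removed],
      hull = hull,
      centroid = colMeans(kept)
    )
  }
  structure(
    list(groups = groups,
         global_centroid = colMeans(do.call(rbind, lapply(groups, `[[`,
                                                          "points"))),
         tau = tau, separation = 0, p = ncol(X)),
    class = "hull_summary"
  )
}

#' Translate hulls apart along their centroid directions
#'
#' Moves each partition's hull in a parallel manner by `s` units in the
#' direction from the center of all points to the hull's own centroid, so
#' hulls near the graph origin become visible.  Shapes are rigid under the
#' translation: all within-group pairwise distances are preserved exactly,
#' and the operation is reversed by `-s`.  A group whose centroid
#' coincides with the global center has no defined direction and stays
#' put.
#'
#' @param summary A `"hull_summary"`.
#' @param s Translation magnitude (>= 0 moves outward; negative reverses).
#' @return The translated `"hull_summary"` (the `separation` field
#'   accumulates `s`; the global centroid is kept at its original value
#'   so repeated calls move along fixed rays).
#' @export
separate_hulls <- function(summary, s) {
  stopifnot(inherits(summary, "hull_summary"))
  stopifnot_scalar_number(s, "s")
  if (s == 0) return(summary)
  ctr <- summary$global_centroid
  for (g in names(summary$groups)) {
    grp <- summary$groups[[g]]
    dir <- grp$centroid - ctr
    len <- sqrt(sum(dir^2))
    if (len == 0) next
    shift <- s * dir / len
    grp$points <- sweep(grp$points, 2L, shift, `+`)
    grp$centroid <- grp$centroid + shift
    summary$groups[[g]] <- grp
  }
  summary$separation <- summary$separation + s
  summary
}

#' @export
print.hull_summary <- function(x, ...) {
  cat(sprintf("hull summary: %d partition(s), tau = %g, separation = %g\n",
              length(x$groups), x$tau, x$separation))
  for (g in names(x$groups)) {
    grp <- x$groups[[g]]
    cat(sprintf("  %s: %d retained, %d removed%s\n", g, nrow(grp$points),
                length(grp$removed),
                if (!is.null(grp$hull) && grp$hull$degenerate)
                  " (degenerate hull)" else ""))
  }
  invisible(x)
}

#' Plot a hull summary (2D, or 3D projected to its first two axes)
#'
#' Base-graphics rendering: points colored by partition, hull outlines per
#' group, removed outliers as open circles.
#'
#' @param x A `"hull_summary"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.hull_summary <- function(x, ...) {
  all_pts <- do.call(rbind, lapply(x$groups, `[[`, "points"))
  cols <- grDevices::hcl.colors(max(length(x$groups), 2L), "Dark 3")
  graphics::plot(all_pts[, 1L], all_pts[, 2L], type = "n",
                 xlab = "axis 1", ylab = "axis 2", ...)
  for (i in seq_along(x$groups)) {
    grp <- x$groups[[i]]
    pts <- grp$points
    graphics::points(pts[, 1L], pts[, 2L], col = cols[i], pch = 16,
                     cex = 0.6)
    hull <- grp$hull
    if (!is.null(hull)) {
      ord <- if (is.matrix(hull$facets)) {
        grDevices::chull(pts[, 1L], pts[, 2L])  # 3D drawn by 2D silhouette
      } else hull$facets
      if (length(ord) >= 2L) {
        graphics::polygon(pts[ord, 1L], pts[ord, 2L], border = cols[i])
      }
    }
  }
  invisible(x)
}
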
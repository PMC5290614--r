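#' Nearest-neighbor structure of a distance matrix
#'
#' Per-point neighbor distances and distance ranks, the shared substrate
#' of the maximum-likelihood and nearest-neighbor dimensionality
#' estimators and of the trustworthiness/continuity diagnostics.  Ties are
#' broken by point index, deterministically.
#'
#' @param delta Dissimilarity matrix or `"rf_dist"`.
#' @param k_max Number of neighbor columns to retain (default N - 1).
#' @return Object of class `"neighbor_structure"`: list with `T` (N x
#'   k_max matrix, `T[i, k]` = distance from i to its k-th nearest
#'   neighbor, self excluded), `order` (N x (N-1) neighbor indices) and
#'   `rank` (N x N matrix, `rank[i, j]` = rank of j in i's ordering, 0 on
#'   the diagonal).
#' @export
neighbor_structure <- function(delta, k_max = NULL) {
  delta <- as_delta_matrix(delta)
  n <- nrow(delta)
  if (is.null(k_max)) k_max <- n - 1L
  k_max <- as.integer(k_max)
  stopifnot(k_max >= 1L, k_max <= n - 1L)
  Tm <- matrix(0, n, k_max)
  ord <- matrix(0L, n, n - 1L)
  rnk <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    o <- others[order(delta[i, others], others)]  # ties -> lowest index
    ord[i, ] <- o
    rnk[i, o] <- seq_len(n - 1L)
    Tm[i, ] <- delta[i, o[seq_len(k_max)]]
  }
  structure(list(T = Tm, order = ord, rank = rnk, n = n, k_max = k_max),
            class = "neighbor_structure")
}

#' Correlation dimension
#'
#' The correlation integral
#' \eqn{C(r) = \frac{2}{N(N-1)} \#\{i<j : \delta_{ij} < r\}} scales as
#' \eqn{r^D} on a D-dimensional support; the estimate is the slope of the
#' least-squares line of \eqn{\log C(r)} on \eqn{\log r} over the grid
#' points with \eqn{0 < C(r) < 1}.
#'
#' Tree-to-tree RF distances are integers, so C(r) is a step function; the
#' default grid therefore uses 20 quantiles of the distinct positive
#' observed distances, which avoids empty log-log cells.  The quantile
#' range is 2% to 25%: the \eqn{r^D} scaling law holds only at radii small
#' against the diameter of the support, and radii near the upper
#' percentiles saturate C(r) toward 1 (boundary effect), which biases the
#' slope low.
#'
#' @param delta Dissimilarity matrix or `"rf_dist"`.
#' @param r_grid Optional vector of radii.
#' @return A single positive estimate, with attribute `"points"` carrying
#'   the (log r, log C) pairs used.
#' @export
correlation_dimension <- function(delta, r_grid = NULL) {
  delta <- as_delta_matrix(delta)
  off <- delta[upper_mask(nrow(delta))]
  pos <- off[off > 0]
  if (length(pos) == 0L) stop("all distances are zero", call. = FALSE)
  if (is.null(r_grid)) {
    qs <- stats::quantile(unique(pos), probs = seq(0.02, 0.25, length.out = 20),
                          names = FALSE, type = 7)
    r_grid <- unique(qs)
  }
  r_grid <- sort(r_grid[r_grid > 0])
  C <- vapply(r_grid, function(r) mean(off < r), numeric(1))
  usable <- C > 0 & C < 1
  if (sum(usable) < 3L) {
    stop("fewer than 3 usable radii with 0 < C(r) < 1; widen the grid",
         call. = FALSE)
  }
  x <- log(r_grid[usable])
  y <- log(C[usable])
  slope <- stats::coef(stats::lm(y ~ x))[["x"]]
  structure(slope, points = cbind(log_r = x, log_C = y))
}

#' Maximum-likelihood intrinsic dimensionality (Levina-Bickel)
#'
#' For each point i and neighbor count k, the local estimate is
#' \deqn{\hat m_k(i) = \left[\frac{1}{k-1} \sum_{j=1}^{k-1}
#'   \log\frac{T_{ik}}{T_{ij}}\right]^{-1},}
#' the inverse mean log-ratio of the k-th neighbor distance to the nearer
#' ones.  The global estimate averages \eqn{\hat m_k(i)} over points and
#' over \eqn{k \in [k_1, k_2]} (default 6..12, the range recommended by
#' the estimator's source).  Zero neighbor distances (duplicate points,
#' frequent with RF ties) are excluded from the inner sum; a point whose
#' usable terms vanish at some k is skipped there.
#'
#' @param ns A `"neighbor_structure"` (with `k_max >= k2`).
#' @param k1,k2 Neighbor-count range.
#' @return Positive scalar estimate.
#' @export
ml_dimension <- function(ns, k1 = 6L, k2 = 12L) {
  stopifnot(inherits(ns, "neighbor_structure"))
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (!(2L <= k1 && k1 < k2 && k2 <= ns$k_max)) {
    stop("need 2 <= k1 < k2 <= k_max of the neighbor structure", call. = FALSE)
  }
  vals <- c()
  for (k in k1:k2) {
    Tk <- ns$T[, k]
    ratios <- log(Tk / ns$T[, seq_len(k - 1L), drop = FALSE])
    # zero distances give non-finite logs; exclude them per point
    mhat <- apply(ratios, 1L, function(row) {
      row <- row[is.finite(row) & row > 0]
      if (length(row) == 0L) return(NA_real_)
      1 / mean(row)
    })
    vals <- c(vals, mhat[is.finite(mhat)])
  }
  if (length(vals) == 0L) {
    stop("no usable points: all neighbor distances are zero", call. = FALSE)
  }
  mean(vals)
}

# Pettis correction term G(d, k) = k^{1/d} Gamma(k) / Gamma(k + 1/d).
pettis_G <- function(d, k) exp(log(k) / d + lgamma(k) - lgamma(k + 1 / d))

#' Nearest-neighbor intrinsic dimensionality (Pettis)
#'
#' Let \eqn{\bar r_k} be the mean over points of the distance to the k-th
#' nearest neighbor.  On a d-dimensional support, \eqn{\bar r_k \propto
#' k^{1/d}} up to a Gamma-function bias factor.  The raw estimate is the
#' slope of the least-squares fit of \eqn{\log k} on \eqn{\log \bar r_k}
#' for k = 1..k_max; the iterated estimate repeats the fit with each
#' \eqn{\bar r_k} multiplied by the correction
#' \eqn{G(d,k) = k^{1/d}\Gamma(k)/\Gamma(k + 1/d)} until the slope changes
#' by less than 1e-3 (at most 100 iterations).  The iterated value is the
#' headline; the raw slope is returned as an attribute.
#'
#' @param ns A `"neighbor_structure"`.
#' @param k_max Largest neighbor count used (>= 3; default min(20, k_max
#'   available)).
#' @return Positive scalar (iterated estimate) with attribute `"raw"`.
#' @export
nn_dimension <- function(ns, k_max = NULL) {
  stopifnot(inherits(ns, "neighbor_structure"))
  if (is.null(k_max)) k_max <- min(20L, ns$k_max)
  k_max <- as.integer(k_max)
  if (k_max < 3L || k_max > ns$k_max) {
    stop("need 3 <= k_max <= neighbor structure's k_max", call. = FALSE)
  }
  ks <- seq_len(k_max)
  rbar <- colMeans(ns$T[, ks, drop = FALSE])
  if (any(rbar <= 0) || diff(range(rbar)) == 0) {
    stop("degenerate neighbor distances (coincident points?)", call. = FALSE)
  }
  fit_slope <- function(rk) {
    x <- log(rk); y <- log(ks)
    if (diff(range(x)) == 0) stop("all mean neighbor distances equal",
                                  call. = FALSE)
    stats::coef(stats::lm(y ~ x))[["x"]]
  }
  raw <- fit_slope(rbar)
  d <- max(raw, 0.1)
  for (it in seq_len(100L)) {
    corrected <- rbar * pettis_G(d, ks)
    d_new <- max(fit_slope(corrected), 0.1)
    if (abs(d_new - d) < 1e-3) {
      d <- d_new
      break
    }
    d <- d_new
  }
  structure(d, raw = raw)
}

#' Best final stress as a function of target dimension
#'
#' Embeds the same dissimilarities into each candidate dimension with a
#' chosen admissible stress/optimizer pairing (default CCA + SGD) and
#' records the best final stress over restarts.  The elbow of the curve is
#' the classical visual-inspection route to intrinsic dimensionality; the
#' curve itself is always returned, and `inspection_dim` operationalizes
#' the visual call as the smallest dimension whose stress is within 5% of
#' the stress at the largest dimension probed.
#'
#' @param delta Dissimilarity matrix or `"rf_dist"`.
#' @param dims Integer vector of target dimensions.
#' @param stress_name,optimizer_name Admissible pairing (default
#'   `"cca"` + `"sgd"`).
#' @param restarts Restarts per dimension (default 3).
#' @param base_seed Seed for the restarts.
#' @param opt Optional `"optimizer_spec"`.
#' @return Data frame with columns `dim` and `stress`, with attribute
#'   `"inspection_dim"`.
#' @export
stress_vs_dimension <- function(delta, dims, stress_name = "cca",
                                optimizer_name = "sgd", restarts = 3L,
                                base_seed = 1L, opt = optimizer_spec()) {
  assert_admissible(stress_name, optimizer_name)
  if (length(dims) < 1L || any(dims < 1L)) {
    stop("`dims` must be a non-empty vector of dimensions >= 1", call. = FALSE)
  }
  delta <- as_delta_matrix(delta)
  best <- vapply(dims, function(p) {
    b <- run_batch(delta, stress_name, optimizer_name, p = p,
                   n_restarts = restarts,
                   base_seed = derive_seed(base_seed, p), opt = opt)
    min(b$final_stresses)
  }, numeric(1))
  out <- data.frame(dim = as.integer(dims), stress = best)
  ref <- best[which.max(dims)]
  ok <- which(best <= ref * 1.05 + 1e-300)
  attr(out, "inspection_dim") <- if (length(ok)) out$dim[min(ok)] else
    out$dim[which.max(dims)]
  out
}

#' Intrinsic-dimensionality report
#'
#' Runs the three point estimators (and optionally the stress-versus-
#' dimension curve) on one distance matrix and collects them in a single
#' report, the package-level analogue of a dimensionality summary table.
#'
#' @param delta Dissimilarity matrix or `"rf_dist"`.
#' @param dims Dimensions for the stress curve; `NULL` skips it.
#' @param ml_k Range `c(k1, k2)` for [ml_dimension()].
#' @param nn_k_max `k_max` for [nn_dimension()].
#' @param base_seed Seed for the stress curve.
#' @return Object of class `"dim_report"`: list with `nn_estimate`,
#'   `cor_estimate`, `ml_estimate`, `stress_curve` (data frame or `NULL`)
#'   and `inspection_dim`.
#' @export
dim_report <- function(delta, dims = NULL, ml_k = c(6L, 12L),
                       nn_k_max = NULL, base_seed = 1L) {
  delta <- as_delta_matrix(delta)
  ns <- neighbor_structure(delta, k_max = min(nrow(delta) - 1L,
                                              max(ml_k[2], 20L)))
  curve <- NULL
  inspection <- NA_integer_
  if (!is.null(dims)) {
    curve <- stress_vs_dimension(delta, dims, base_seed = base_seed)
    inspection <- attr(curve, "inspection_dim")
  }
  structure(
    list(
      nn_estimate = as.numeric(nn_dimension(ns, k_max = nn_k_max)),
      cor_estimate = as.numeric(correlation_dimension(delta)),
      ml_estimate = ml_dimension(ns, ml_k[1], ml_k[2]),
      stress_curve = curve,
      inspection_dim = inspection
    ),
    class = "dim_report"
  )
}

#' @export
print.dim_report <- function(x, ...) {
  cat("intrinsic dimensionality estimates\n")
  cat(sprintf("  nearest-neighbor: %.2f\n", x$nn_estimate))
  cat(sprintf("  correlation:      %.2f\n", x$cor_estimate))
  cat(sprintf("  max-likelihood:   %.2f\n", x$ml_estimate))
  if (!is.null(x$stress_curve)) {
    cat(sprintf("  stress-curve inspection dim: %d\n", x$inspection_dim))
  }
  invisible(x)
}
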
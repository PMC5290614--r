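#' Pairwise Euclidean distances of an embedding
#'
#' @param X N x p coordinate matrix.
#' @return N x N symmetric matrix with zero diagonal.
#' @export
embedded_distances <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("coordinates must be finite", call. = FALSE)
  d <- as.matrix(stats::dist(X))
  dimnames(d) <- NULL
  d
}

#' Stress specification
#'
#' Bundles the stress-function choice with its numerical knobs.  The four
#' stresses measure the discrepancy between input dissimilarities
#' \eqn{\delta_{ij}} and embedded Euclidean distances \eqn{d_{ij}} over
#' unordered pairs i < j:
#' \describe{
#'   \item{normalized}{\eqn{\sum (\delta - d)^2 / \sum \delta^2}}
#'   \item{kruskal1}{\eqn{\sqrt{\sum (\delta - d)^2 / \sum d^2}}}
#'   \item{nlm}{Sammon's nonlinear mapping,
#'     \eqn{(1/\sum' \delta)\sum' (\delta - d)^2/\delta}, the primed sums
#'     skipping pairs with \eqn{\delta = 0} (duplicate topologies)}
#'   \item{cca}{curvilinear components analysis,
#'     \eqn{\sum (\delta - d)^2 F(d, \lambda)} with the step weight
#'     \eqn{F(d,\lambda) = 1} if \eqn{d \le \lambda}, else 0.  The weight
#'     depends on the embedded (output) distance, which is what lets the
#'     embedding "tear" a manifold: distant pairs whose embedded distance
#'     has exceeded the shrinking neighborhood radius \eqn{\lambda} stop
#'     contributing.}
#' }
#'
#' @param name One of `"normalized"`, `"kruskal1"`, `"nlm"`, `"cca"`.
#' @param cca_lambda0 Initial CCA radius; default `NA` = max \eqn{\delta}
#'   (resolved when the optimizer sees the data).
#' @param cca_lambda_end Final CCA radius; default `NA` = 0.05 max
#'   \eqn{\delta}.  Decays geometrically per optimizer sweep.
#' @param eps Guard for zero embedded distances in gradients.
#' @return Object of class `"stress_spec"`.
#' @export
stress_spec <- function(name = c("normalized", "kruskal1", "nlm", "cca"),
                        cca_lambda0 = NA_real_, cca_lambda_end = NA_real_,
                        eps = 1e-12) {
  name <- match.arg(name)
  if (!is.na(cca_lambda0) && !is.na(cca_lambda_end) &&
      !(cca_lambda0 >= cca_lambda_end && cca_lambda_end > 0)) {
    stop("need cca_lambda0 >= cca_lambda_end > 0", call. = FALSE)
  }
  structure(
    list(name = name, cca_lambda0 = cca_lambda0,
         cca_lambda_end = cca_lambda_end, eps = eps),
    class = "stress_spec"
  )
}

# Resolve the lambda schedule endpoints against the data scale.
resolve_lambda <- function(spec, delta) {
  dmax <- max(delta)
  l0 <- if (is.na(spec$cca_lambda0)) dmax else spec$cca_lambda0
  l1 <- if (is.na(spec$cca_lambda_end)) 0.05 * dmax else spec$cca_lambda_end
  if (!(l0 >= l1 && l1 > 0)) stop("invalid lambda schedule", call. = FALSE)
  c(l0, l1)
}

#' Normalized stress
#'
#' \eqn{\sum_{i<j} (\delta_{ij} - d_{ij})^2 / \sum_{i<j} \delta_{ij}^2}.
#'
#' @param delta,d Matching symmetric matrices of input dissimilarities and
#'   embedded distances.
#' @return Nonnegative scalar; 0 iff d reproduces delta.
#' @export
stress_normalized <- function(delta, d) {
  m <- upper_mask(nrow(delta))
  denom <- sum(delta[m]^2)
  if (denom == 0) stop("all input dissimilarities are zero", call. = FALSE)
  sum((delta[m] - d[m])^2) / denom
}

#' Kruskal-1 stress
#'
#' \eqn{\sqrt{\sum_{i<j} (\delta_{ij} - d_{ij})^2 / \sum_{i<j} d_{ij}^2}}.
#' Invariant to rescaling delta and d together.
#'
#' @inheritParams stress_normalized
#' @return Nonnegative scalar.
#' @export
stress_kruskal1 <- function(delta, d) {
  m <- upper_mask(nrow(delta))
  denom <- sum(d[m]^2)
  if (denom == 0) stop("embedded distances are all zero", call. = FALSE)
  sqrt(sum((delta[m] - d[m])^2) / denom)
}

#' Sammon (nonlinear mapping) stress
#'
#' \eqn{(1/\sum' \delta_{ij}) \sum' (\delta_{ij} - d_{ij})^2 / \delta_{ij}},
#' the primed sums running over pairs i < j with \eqn{\delta_{ij} > 0};
#' zero-dissimilarity pairs (duplicate topologies) are excluded from both
#' sums.
#'
#' @inheritParams stress_normalized
#' @return Nonnegative scalar.
#' @export
stress_nlm <- function(delta, d) {
  m <- upper_mask(nrow(delta))
  keep <- m & delta > 0
  c_norm <- sum(delta[keep])
  if (c_norm == 0) stop("all input dissimilarities are zero", call. = FALSE)
  sum((delta[keep] - d[keep])^2 / delta[keep]) / c_norm
}

#' CCA stress
#'
#' \eqn{\sum_{i<j} (\delta_{ij} - d_{ij})^2 F(d_{ij}, \lambda)} with the
#' step weight \eqn{F(d, \lambda) = 1\{d \le \lambda\}} on the embedded
#' distance.  Raw CCA values are not comparable across runs with different
#' \eqn{\lambda} schedules.
#'
#' @inheritParams stress_normalized
#' @param lambda Positive neighborhood radius.
#' @return Nonnegative scalar.
#' @export
stress_cca <- function(delta, d, lambda) {
  stopifnot_scalar_number(lambda, "lambda", positive = TRUE)
  m <- upper_mask(nrow(delta))
  w <- as.numeric(d[m] <= lambda)
  sum((delta[m] - d[m])^2 * w)
}

# Evaluate any stress by name; lambda only used for cca.
stress_value <- function(name, delta, d, lambda = NULL) {
  switch(name,
    normalized = stress_normalized(delta, d),
    kruskal1 = stress_kruskal1(delta, d),
    nlm = stress_nlm(delta, d),
    cca = stress_cca(delta, d, lambda),
    stop(sprintf("unknown stress '%s'", name), call. = FALSE)
  )
}

#' Analytic stress gradient
#'
#' Gradient of the selected stress with respect to the embedding
#' coordinates.  For the CCA stress the step weight is held
#' piecewise-constant (the subgradient at the discontinuity takes the
#' interior branch), so the gradient is that of the weighted squared error
#' with frozen weights.
#'
#' Pairs with \eqn{d_{ij} = 0} contribute nothing (the spherically
#' symmetric subgradient at a coincident pair is taken as zero), and pairs
#' with \eqn{\delta_{ij} = 0} are excluded for the NLM stress.
#'
#' @param spec A `"stress_spec"`.
#' @param delta Input dissimilarity matrix.
#' @param X N x p coordinates.
#' @param lambda CCA radius (required when `spec$name == "cca"`).
#' @return N x p gradient matrix.
#' @export
stress_gradient <- function(spec, delta, X, lambda = NULL) {
  stopifnot(inherits(spec, "stress_spec"))
  X <- as.matrix(X)
  n <- nrow(X)
  d <- embedded_distances(X)
  m <- upper_mask(n)
  dd <- d
  dd[dd < spec$eps] <- spec$eps  # guard: terms with d ~ 0 get zeroed below
  pos <- d > 0
  # dS/dd for each unordered pair, stored symmetrically
  g <- matrix(0, n, n)
  if (spec$name == "normalized") {
    denom <- sum(delta[m]^2)
    if (denom == 0) stop("all input dissimilarities are zero", call. = FALSE)
    g <- -2 * (delta - d) / denom
  } else if (spec$name == "kruskal1") {
    A <- sum((delta[m] - d[m])^2)
    B <- sum(d[m]^2)
    if (B == 0) stop("embedded distances are all zero", call. = FALSE)
    S <- sqrt(A / B)
    if (S == 0) return(matrix(0, n, ncol(X)))
    g <- (-2 * (delta - d) * B - A * 2 * d) / (2 * S * B^2)
  } else if (spec$name == "nlm") {
    keep <- delta > 0
    c_norm <- sum(delta[m & keep])
    if (c_norm == 0) stop("all input dissimilarities are zero", call. = FALSE)
    g[keep] <- (-2 * (delta[keep] - d[keep]) / delta[keep]) / c_norm
  } else if (spec$name == "cca") {
    if (is.null(lambda)) stop("cca gradient needs `lambda`", call. = FALSE)
    w <- (d <= lambda) * 1
    g <- -2 * (delta - d) * w
  }
  diag(g) <- 0
  # chain rule: dd_ij/dx_i = (x_i - x_j)/d_ij
  W <- g / dd
  W[!pos] <- 0
  diag(W) <- 0
  rs <- rowSums(W)
  rs * X - W %*% X
}
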
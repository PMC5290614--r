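#' Optimizer specification
#'
#' Hyperparameters for the five embedding optimizers.  All are exposed;
#' the defaults were chosen to converge on the package's property-test
#' suite and are documented in the methods vignette.
#'
#' @param max_sweeps Sweep budget (one sweep visits every point or pair).
#' @param tol Relative stress change below which a run is converged; the
#'   criterion must hold over `tol_sweeps` consecutive sweeps, which makes
#'   it robust to stochastic-gradient noise.
#' @param tol_sweeps Consecutive sweeps required for convergence.
#' @param alpha0,tau SGD step schedule \eqn{\alpha_t = \alpha_0/(1 + t/\tau)}
#'   with t the sweep index.
#' @param t0_scale MCMC initial temperature = initial stress / N, times
#'   this factor (default 0.1: the raw stress/N scale is hot relative to
#'   single-point stress changes, especially for the square-root-scaled
#'   Kruskal-1 stress).
#' @param cooling Geometric cooling factor per MCMC sweep, in (0,1).
#' @param sigma_frac MCMC proposal: Gaussian perturbation of one point
#'   with initial sd = `sigma_frac` times the coordinate range; the sd
#'   then adapts to the acceptance rate (grown above 30%, shrunk below
#'   20%) so proposals refine as the chain cools.
#' @param eta Linear-iteration fixed step, in units of the squared mean
#'   positive dissimilarity (which makes the step invariant to a global
#'   rescaling of the input distances).
#' @return Object of class `"optimizer_spec"`.
#' @export
optimizer_spec <- function(max_sweeps = 1000L, tol = 1e-6, tol_sweeps = 10L,
                           alpha0 = 0.2, tau = 100, t0_scale = 0.1,
                           cooling = 0.99, sigma_frac = 0.05, eta = 0.3) {
  stopifnot(max_sweeps >= 1L, tol > 0, cooling > 0, cooling < 1)
  structure(
    list(max_sweeps = as.integer(max_sweeps), tol = tol,
         tol_sweeps = as.integer(tol_sweeps), alpha0 = alpha0, tau = tau,
         t0_scale = t0_scale, cooling = cooling, sigma_frac = sigma_frac,
         eta = eta),
    class = "optimizer_spec"
  )
}

#' The 14 admissible stress-by-optimizer pairings
#'
#' Of the 16 combinations of the four stress functions with the four main
#' optimizers, two are excluded (majorization with CCA, Gauss-Seidel-Newton
#' with CCA) and one is substituted: stochastic gradient descent with
#' Kruskal-1 is replaced by Kruskal-1 with a fixed-step steepest-descent
#' ("linear iteration").  That leaves exactly 14 runnable pairings.
#'
#' @return Data frame with columns `stress` and `optimizer`, 14 rows.
#' @export
admissible_pairs <- function() {
  rows <- rbind(
    expand.grid(stress = c("normalized", "kruskal1", "nlm"),
                optimizer = c("majorization", "gauss_seidel_newton", "mcmc"),
                stringsAsFactors = FALSE),
    expand.grid(stress = c("normalized", "nlm"), optimizer = "sgd",
                stringsAsFactors = FALSE),
    expand.grid(stress = "cca", optimizer = c("sgd", "mcmc"),
                stringsAsFactors = FALSE),
    data.frame(stress = "kruskal1", optimizer = "linear_iteration",
               stringsAsFactors = FALSE)
  )
  rownames(rows) <- NULL
  rows
}

is_admissible <- function(stress_name, optimizer_name) {
  ap <- admissible_pairs()
  any(ap$stress == stress_name & ap$optimizer == optimizer_name)
}

assert_admissible <- function(stress_name, optimizer_name) {
  if (!is_admissible(stress_name, optimizer_name)) {
    stop(sprintf(
      paste0("(%s, %s) is not one of the 14 admissible stress/optimizer ",
             "pairings: CCA runs only with sgd or mcmc, and Kruskal-1 uses ",
             "linear_iteration in place of sgd"),
      stress_name, optimizer_name
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Random initial configuration
#'
#' Coordinates drawn i.i.d. uniform on `[0, max delta]` per axis, so the
#' initial spread matches the scale of the input dissimilarities.
#'
#' @param delta Dissimilarity matrix (or `"rf_dist"`).
#' @param p Target dimension.
#' @param seed Integer seed; the draw is deterministic given the seed and
#'   does not disturb the caller's RNG stream.
#' @return N x p matrix.
#' @export
initialize_embedding <- function(delta, p, seed) {
  delta <- as_delta_matrix(delta)
  stopifnot(p >= 1L)
  n <- nrow(delta)
  hi <- max(delta)
  if (hi == 0) hi <- 1
  with_seed(seed, matrix(stats::runif(n * p, 0, hi), nrow = n, ncol = p))
}

new_embedding <- function(X, stress_name, optimizer_name, seed,
                          final_stress, runtime_seconds, trace, sweeps,
                          converged = NA) {
  structure(
    list(X = X, p = ncol(X), stress_name = stress_name,
         optimizer_name = optimizer_name, seed = seed,
         final_stress = final_stress, runtime_seconds = runtime_seconds,
         trace = trace, sweeps = sweeps, converged = converged),
    class = "embedding"
  )
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf(
    "embedding: %d points in %dD | %s + %s | final stress %.6g (%d sweeps)\n",
    nrow(x$X), x$p, x$stress_name, x$optimizer_name, x$final_stress,
    x$sweeps
  ))
  invisible(x)
}

# Has the trace met the convergence criterion (relative change < tol over
# the last `tol_sweeps` transitions)?
trace_converged <- function(trace, tol, tol_sweeps) {
  k <- length(trace)
  if (k < tol_sweeps + 1L) return(FALSE)
  recent <- trace[(k - tol_sweeps):k]
  denom <- pmax(abs(recent[-length(recent)]), 1e-300)
  steps <- abs(diff(recent))
  all(steps / denom < tol | steps < 1e-14)
}

## ---- majorization (SMACOF) ------------------------------------------------

#' SMACOF majorization
#'
#' Each sweep replaces the configuration by the Guttman transform: the
#' exact minimizer of the quadratic majorizer of the weighted squared-error
#' stress (weights 1 for the normalized and Kruskal-1 pairings, 1/delta for
#' Sammon/NLM).  The majorized objective is guaranteed non-increasing sweep
#' to sweep; the `trace` records it on the normalized-stress scale (for the
#' Kruskal-1 pairing, the reported `final_stress` is the Kruskal-1 value of
#' the final configuration, whose own trace the surrogate does not bound).
#'
#' @param delta Dissimilarity matrix.
#' @param spec A `"stress_spec"` with name in
#'   `c("normalized", "kruskal1", "nlm")`.
#' @param X0 Initial N x p configuration.
#' @param opt An `"optimizer_spec"`.
#' @param seed Seed recorded in the result (the iteration itself is
#'   deterministic).
#' @return An `"embedding"`.
#' @export
run_majorization <- function(delta, spec, X0, opt = optimizer_spec(),
                             seed = NA_integer_) {
  t_start <- proc.time()[["elapsed"]]
  delta <- as_delta_matrix(delta)
  if (!spec$name %in% c("normalized", "kruskal1", "nlm")) {
    stop("majorization supports normalized, kruskal1 and nlm stress",
         call. = FALSE)
  }
  n <- nrow(delta)
  m <- upper_mask(n)
  if (sum(delta[m]^2) == 0) stop("degenerate input: all dissimilarities zero",
                                 call. = FALSE)
  W <- if (spec$name == "nlm") {
    w <- 1 / delta
    w[!is.finite(w)] <- 0
    w
  } else {
    matrix(1, n, n) - diag(n)
  }
  diag(W) <- 0
  # surrogate objective sigma_w(X) scaled to a stress-like quantity
  surrogate_scale <- if (spec$name == "nlm") sum(delta[m]) else sum(delta[m]^2)
  V <- diag(rowSums(W)) - W
  # V is singular on the all-ones vector; add J/n, which leaves the
  # centered Guttman transform unchanged.
  solver <- solve(V + matrix(1 / n, n, n))
  X <- as.matrix(X0)
  d <- embedded_distances(X)
  surrogate <- function(d) sum(W[m] * (delta[m] - d[m])^2) / surrogate_scale
  trace <- surrogate(d)
  sweeps <- 0L
  for (s in seq_len(opt$max_sweeps)) {
    ratio <- W * delta / d
    ratio[d == 0] <- 0
    diag(ratio) <- 0
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X <- solver %*% (B %*% X)
    d <- embedded_distances(X)
    trace <- c(trace, surrogate(d))
    sweeps <- s
    if (trace_converged(trace, opt$tol, opt$tol_sweeps)) break
  }
  final <- stress_value(spec$name, delta, d)
  new_embedding(X, spec$name, "majorization", seed, final,
                proc.time()[["elapsed"]] - t_start, trace, sweeps,
                converged = sweeps < opt$max_sweeps)
}

## ---- incremental single-point stress state --------------------------------

# Mutable state for optimizers that move one point at a time (GSN, MCMC).
# Tracks the embedded-distance matrix and the stress components so a
# single-point move costs O(N), not O(N^2).
make_point_state <- function(name, delta, X, lambda = NULL) {
  n <- nrow(delta)
  m <- upper_mask(n)
  st <- new.env(parent = emptyenv())
  st$name <- name
  st$delta <- delta
  st$X <- as.matrix(X)
  st$d <- embedded_distances(st$X)
  st$lambda <- lambda
  st$n <- n
  if (name == "normalized") {
    st$Cdelta <- sum(delta[m]^2)
    if (st$Cdelta == 0) stop("degenerate input: all dissimilarities zero",
                             call. = FALSE)
    st$A <- sum((delta[m] - st$d[m])^2)
  } else if (name == "kruskal1") {
    st$A <- sum((delta[m] - st$d[m])^2)
    st$B <- sum(st$d[m]^2)
  } else if (name == "nlm") {
    st$wnlm <- 1 / delta
    st$wnlm[!is.finite(st$wnlm)] <- 0
    diag(st$wnlm) <- 0
    st$c_norm <- sum(delta[m])
    if (st$c_norm == 0) stop("degenerate input: all dissimilarities zero",
                             call. = FALSE)
    st$A <- sum(st$wnlm[m] * (delta[m] - st$d[m])^2)
  } else if (name == "cca") {
    st$A <- sum(((delta[m] - st$d[m])^2)[st$d[m] <= lambda])
  } else {
    stop(sprintf("unknown stress '%s'", name), call. = FALSE)
  }
  st
}

point_state_stress <- function(st) {
  switch(st$name,
    normalized = st$A / st$Cdelta,
    kruskal1 = if (st$B <= 0) Inf else sqrt(max(st$A, 0) / st$B),
    nlm = st$A / st$c_norm,
    cca = st$A
  )
}

# Reset the CCA radius (recomputes the weighted error sum).
point_state_set_lambda <- function(st, lambda) {
  st$lambda <- lambda
  m <- upper_mask(st$n)
  st$A <- sum(((st$delta[m] - st$d[m])^2)[st$d[m] <= lambda])
  invisible(st)
}

# Stress change if point i moved to xnew; returns the proposal without
# committing it.
point_state_propose <- function(st, i, xnew) {
  xi <- st$X[i, ]
  diffs <- sweep(st$X, 2L, xnew, `-`)
  dnew <- sqrt(rowSums(diffs^2))
  dnew[i] <- 0
  dold <- st$d[, i]
  deli <- st$delta[, i]
  keep <- seq_len(st$n) != i
  dnew_k <- dnew[keep]; dold_k <- dold[keep]; del_k <- deli[keep]
  prop <- list(dnew = dnew)
  if (st$name == "normalized") {
    prop$A <- max(st$A + sum((del_k - dnew_k)^2 - (del_k - dold_k)^2), 0)
    prop$stress <- prop$A / st$Cdelta
  } else if (st$name == "kruskal1") {
    prop$A <- max(st$A + sum((del_k - dnew_k)^2 - (del_k - dold_k)^2), 0)
    prop$B <- max(st$B + sum(dnew_k^2 - dold_k^2), 0)
    prop$stress <- if (prop$B <= 0) Inf else sqrt(prop$A / prop$B)
  } else if (st$name == "nlm") {
    w_k <- st$wnlm[keep, i]
    prop$A <- max(st$A + sum(w_k * ((del_k - dnew_k)^2 - (del_k - dold_k)^2)), 0)
    prop$stress <- prop$A / st$c_norm
  } else if (st$name == "cca") {
    new_terms <- (del_k - dnew_k)^2 * (dnew_k <= st$lambda)
    old_terms <- (del_k - dold_k)^2 * (dold_k <= st$lambda)
    prop$A <- max(st$A + sum(new_terms - old_terms), 0)
    prop$stress <- prop$A
  }
  prop
}

point_state_commit <- function(st, i, xnew, prop) {
  st$X[i, ] <- xnew
  st$d[, i] <- prop$dnew
  st$d[i, ] <- prop$dnew
  st$A <- prop$A
  if (!is.null(prop$B)) st$B <- prop$B
  invisible(st)
}

# Gradient and diagonal (Gauss-Newton) Hessian of the stress restricted to
# point i, from the incremental state.
point_grad_hess <- function(st, i, eps = 1e-12) {
  keep <- seq_len(st$n) != i
  d_i <- st$d[keep, i]
  del_i <- st$delta[keep, i]
  diffs <- sweep(st$X[keep, , drop = FALSE], 2L, st$X[i, ], `-`)
  dsafe <- pmax(d_i, eps)
  # per-pair dS/dd and squared-error weight for the Hessian approximation
  if (st$name == "normalized") {
    dSdd <- -2 * (del_i - d_i) / st$Cdelta
    w <- rep(2 / st$Cdelta, length(d_i))
  } else if (st$name == "kruskal1") {
    S <- point_state_stress(st)
    if (!is.finite(S) || S == 0) {
      return(list(g = rep(0, ncol(st$X)), h = rep(1, ncol(st$X))))
    }
    dSdd <- (-2 * (del_i - d_i) * st$B - st$A * 2 * d_i) / (2 * S * st$B^2)
    w <- rep(1 / (S * st$B), length(d_i))
  } else if (st$name == "nlm") {
    w_i <- st$wnlm[keep, i]
    dSdd <- -2 * w_i * (del_i - d_i) / st$c_norm
    w <- 2 * w_i / st$c_norm
  } else if (st$name == "cca") {
    F_i <- (d_i <= st$lambda) * 1
    dSdd <- -2 * (del_i - d_i) * F_i
    w <- 2 * F_i
  }
  unit <- -diffs / dsafe            # d d_i / d x_i = (x_i - x_j)/d
  unit[d_i == 0, ] <- 0
  g <- colSums(dSdd * unit)
  h <- colSums(w * unit^2)
  list(g = g, h = h)
}

## ---- Gauss-Seidel-Newton ---------------------------------------------------

# One damped-Newton update of point i in place; halves the step (up to 10
# times) if the stress would increase, falling back to a plain gradient
# step when the curvature is not usable.
gsn_update_point <- function(st, i, grad_step = 0.1, max_halvings = 10L) {
  gh <- point_grad_hess(st, i)
  usable <- is.finite(gh$h) & gh$h > 1e-12
  step <- numeric(length(gh$g))
  step[usable] <- -gh$g[usable] / gh$h[usable]
  if (any(!usable)) {
    scale <- max(abs(st$X)) + 1
    step[!usable] <- -grad_step * scale * gh$g[!usable] /
      (max(abs(gh$g)) + 1e-300)
  }
  s0 <- point_state_stress(st)
  fac <- 1
  for (h in seq_len(max_halvings + 1L)) {
    xnew <- st$X[i, ] + fac * step
    prop <- point_state_propose(st, i, xnew)
    if (prop$stress <= s0 + 1e-15) {
      point_state_commit(st, i, xnew, prop)
      return(TRUE)
    }
    fac <- fac / 2
  }
  FALSE
}

#' Gauss-Seidel-Newton optimization
#'
#' Cycles point by point; each point's coordinates are updated by a damped
#' Newton step using the analytic gradient and a diagonal Gauss-Newton
#' Hessian approximation of the stress restricted to that point, applied
#' in place so later points see earlier updates.  A step that would
#' increase the stress is halved (up to 10 times) before being rejected;
#' unusable curvature falls back to a safeguarded gradient step.
#'
#' @inheritParams run_majorization
#' @return An `"embedding"`.
#' @export
run_gauss_seidel_newton <- function(delta, spec, X0, opt = optimizer_spec(),
                                    seed = NA_integer_) {
  t_start <- proc.time()[["elapsed"]]
  delta <- as_delta_matrix(delta)
  if (!spec$name %in% c("normalized", "kruskal1", "nlm")) {
    stop("gauss_seidel_newton supports normalized, kruskal1 and nlm stress",
         call. = FALSE)
  }
  st <- make_point_state(spec$name, delta, as.matrix(X0))
  trace <- point_state_stress(st)
  sweeps <- 0L
  for (s in seq_len(opt$max_sweeps)) {
    for (i in seq_len(st$n)) gsn_update_point(st, i)
    trace <- c(trace, point_state_stress(st))
    sweeps <- s
    if (trace_converged(trace, opt$tol, opt$tol_sweeps)) break
  }
  new_embedding(st$X, spec$name, "gauss_seidel_newton", seed,
                point_state_stress(st),
                proc.time()[["elapsed"]] - t_start, trace, sweeps,
                converged = sweeps < opt$max_sweeps)
}

## ---- stochastic gradient descent ------------------------------------------

#' Stochastic gradient descent
#'
#' For the normalized and Sammon/NLM stresses, each sweep visits all
#' unordered pairs in a seeded random order and applies the per-pair
#' gradient step to both endpoints with step size
#' \eqn{\alpha_t = \alpha_0/(1 + t/\tau)} (t = sweep index).  For the CCA
#' stress the sweep instead visits every point as a pivot and moves all
#' other points toward or away from it along the connecting direction,
#' weighted by the step function of the embedded distance; the
#' neighborhood radius \eqn{\lambda} decays geometrically per sweep from
#' `cca_lambda0` to `cca_lambda_end` (defaults: max delta down to 5% of
#' it).  Convergence is assessed on the full stress each sweep (for CCA,
#' only once the radius has reached its final value, since the raw CCA
#' stress is not comparable across radii).
#'
#' @inheritParams run_majorization
#' @param seed Seed for the visiting order (and recorded provenance).
#' @return An `"embedding"`.
#' @export
run_sgd <- function(delta, spec, X0, opt = optimizer_spec(),
                    seed = NA_integer_) {
  t_start <- proc.time()[["elapsed"]]
  delta <- as_delta_matrix(delta)
  if (!spec$name %in% c("normalized", "nlm", "cca")) {
    stop("sgd supports normalized, nlm and cca stress", call. = FALSE)
  }
  n <- nrow(delta)
  m <- upper_mask(n)
  Xt <- t(as.matrix(X0))  # p x n: column access is cheap in the inner loop
  eps <- spec$eps
  run <- with_seed(seed, {
    if (spec$name == "cca") {
      lam <- resolve_lambda(spec, delta)
      decay <- if (opt$max_sweeps > 1L) {
        (lam[2] / lam[1])^(1 / (opt$max_sweeps - 1L))
      } else 1
      lambda <- lam[1]
      trace <- stress_cca(delta, embedded_distances(t(Xt)), lambda)
      sweeps <- 0L
      for (s in seq_len(opt$max_sweeps)) {
        alpha <- opt$alpha0 / (1 + (s - 1) / opt$tau)
        for (i in sample.int(n)) {
          diffs <- Xt - Xt[, i]
          d_i <- sqrt(colSums(diffs^2))
          w <- as.numeric(d_i <= lambda)
          w[i] <- 0
          fac <- alpha * w * (delta[, i] - d_i) / pmax(d_i, eps)
          fac[d_i == 0] <- 0
          Xt <- Xt + diffs * rep(fac, each = nrow(Xt))
        }
        at_end <- lambda <= lam[2] * 1.0001
        lambda <- max(lambda * decay, lam[2])
        trace <- c(trace, stress_cca(delta, embedded_distances(t(Xt)),
                                     lambda))
        sweeps <- s
        if (at_end && trace_converged(trace, opt$tol, opt$tol_sweeps)) break
      }
      list(Xt = Xt, trace = trace, sweeps = sweeps)
    } else {
      pairs <- which(m, arr.ind = TRUE)  # all i < j
      if (spec$name == "normalized") {
        norm_c <- sum(delta[m]^2)
        if (norm_c == 0) stop("degenerate input: all dissimilarities zero",
                              call. = FALSE)
        # per-pair weight brings the raw step onto the data scale
        wts <- rep(n / 2, nrow(pairs))
      } else {
        keep <- delta[m] > 0
        pairs <- pairs[keep, , drop = FALSE]
        c_norm <- sum(delta[m])
        if (c_norm == 0) stop("degenerate input: all dissimilarities zero",
                              call. = FALSE)
        invd <- 1 / delta[pairs]
        # normalize the 1/delta weights to unit mean and cap them so a
        # few near-duplicate pairs cannot destabilize the steps
        wts <- (n / 2) * pmin(invd / mean(invd), 10)
      }
      stress_fun <- function() {
        stress_value(spec$name, delta, embedded_distances(t(Xt)))
      }
      trace <- stress_fun()
      sweeps <- 0L
      npair <- nrow(pairs)
      for (s in seq_len(opt$max_sweeps)) {
        alpha <- opt$alpha0 / (1 + (s - 1) / opt$tau)
        for (k in sample.int(npair)) {
          i <- pairs[k, 1L]; j <- pairs[k, 2L]
          diff <- Xt[, i] - Xt[, j]
          dij <- sqrt(sum(diff^2))
          if (dij < eps) next
          # gradient of this pair's residual, scaled by alpha/n so a full
          # sweep makes O(alpha)-sized total moves
          gstep <- alpha * wts[k] * (delta[i, j] - dij) / (n * dij) * diff
          Xt[, i] <- Xt[, i] + gstep
          Xt[, j] <- Xt[, j] - gstep
        }
        trace <- c(trace, stress_fun())
        sweeps <- s
        if (trace_converged(trace, opt$tol, opt$tol_sweeps)) break
      }
      list(Xt = Xt, trace = trace, sweeps = sweeps)
    }
  })
  X <- t(run$Xt)
  d <- embedded_distances(X)
  lambda_final <- if (spec$name == "cca") resolve_lambda(spec, delta)[2] else NULL
  final <- stress_value(spec$name, delta, d, lambda_final)
  new_embedding(X, spec$name, "sgd", seed, final,
                proc.time()[["elapsed"]] - t_start, run$trace, run$sweeps,
                converged = run$sweeps < opt$max_sweeps)
}

## ---- MCMC simulated annealing ----------------------------------------------

#' MCMC simulated annealing
#'
#' Metropolis sampler over configurations: each proposal perturbs one
#' point by a Gaussian step and is accepted with probability
#' \eqn{\min(1, e^{-\Delta S/T})}.  The temperature starts at the initial
#' stress divided by N (times `t0_scale`) and cools geometrically per
#' sweep; the proposal sd starts at 5% of the coordinate range and adapts
#' to the acceptance rate, so the chain refines as it cools.  The best-stress state ever visited is
#' returned (annealing may wander after finding a minimum).  For the CCA
#' stress the radius follows the same per-sweep geometric schedule as SGD,
#' and the best state is tracked only at the final radius.
#'
#' @inheritParams run_sgd
#' @return An `"embedding"` (trace = stress after each sweep).
#' @export
run_mcmc <- function(delta, spec, X0, opt = optimizer_spec(),
                     seed = NA_integer_) {
  t_start <- proc.time()[["elapsed"]]
  delta <- as_delta_matrix(delta)
  n <- nrow(delta)
  p <- ncol(as.matrix(X0))
  lam <- if (spec$name == "cca") resolve_lambda(spec, delta) else c(NA, NA)
  lambda <- lam[1]
  st <- make_point_state(spec$name, delta, as.matrix(X0),
                         lambda = if (spec$name == "cca") lambda else NULL)
  decay <- if (spec$name == "cca" && opt$max_sweeps > 1L) {
    (lam[2] / lam[1])^(1 / (opt$max_sweeps - 1L))
  } else 1
  s_now <- point_state_stress(st)
  T0 <- max(s_now / n, 1e-12) * opt$t0_scale
  temp <- T0
  best_X <- st$X
  best_stress <- if (spec$name == "cca") Inf else s_now
  trace <- s_now
  n_acc <- 0L; n_prop <- 0L
  coord_range <- max(apply(st$X, 2L, function(v) diff(range(v))), 1e-8)
  sigma <- opt$sigma_frac * coord_range
  with_seed(seed, {
    for (s in seq_len(opt$max_sweeps)) {
      acc_sweep <- 0L
      for (i in sample.int(n)) {
        xnew <- st$X[i, ] + stats::rnorm(p, sd = sigma)
        prop <- point_state_propose(st, i, xnew)
        dS <- prop$stress - point_state_stress(st)
        n_prop <- n_prop + 1L
        if (dS <= 0 || stats::runif(1) < exp(-dS / temp)) {
          point_state_commit(st, i, xnew, prop)
          n_acc <- n_acc + 1L
          acc_sweep <- acc_sweep + 1L
        }
      }
      # adapt the proposal scale to the acceptance rate
      coord_range <- max(apply(st$X, 2L, function(v) diff(range(v))), 1e-8)
      rate <- acc_sweep / n
      if (rate > 0.3) {
        sigma <- min(sigma * 1.1, 0.5 * coord_range)
      } else if (rate < 0.2) {
        sigma <- max(sigma * 0.9, 1e-7 * coord_range)
      }
      s_now <- point_state_stress(st)
      at_final_lambda <- spec$name != "cca" || lambda <= lam[2] * 1.0001
      if (at_final_lambda && s_now < best_stress) {
        best_stress <- s_now
        best_X <- st$X
      }
      trace <- c(trace, s_now)
      temp <- temp * opt$cooling
      if (spec$name == "cca") {
        lambda <- max(lambda * decay, lam[2])
        point_state_set_lambda(st, lambda)
      }
    }
  })
  if (!is.finite(best_stress)) {  # cca with max_sweeps too small to cool
    best_stress <- point_state_stress(st)
    best_X <- st$X
  }
  emb <- new_embedding(best_X, spec$name, "mcmc", seed, best_stress,
                       proc.time()[["elapsed"]] - t_start, trace,
                       opt$max_sweeps, converged = NA)
  emb$acceptance_rate <- n_acc / n_prop
  emb
}

## ---- linear iteration ------------------------------------------------------

#' Fixed-step steepest descent ("linear iteration") on Kruskal-1 stress
#'
#' Classical deterministic steepest descent with a constant step: every
#' sweep sets \eqn{X \leftarrow X - \eta\,\nabla S_{K1}(X)} with no line
#' search, so a descent is not guaranteed and the stress trace may tick
#' upward.  The step is expressed in units of the squared mean positive
#' dissimilarity, which makes the default behave identically under a
#' global rescaling of the input distances.  A step that is far too large
#' does not blow the Kruskal-1 stress up (it saturates below 1 while the
#' configuration inflates), so divergence is detected when the coordinate
#' spread explodes past 5 times the data diameter, or the stress exceeds
#' 1e6 times its initial value, or anything goes non-finite.
#'
#' @inheritParams run_majorization
#' @return An `"embedding"`.
#' @export
run_linear_iteration <- function(delta, spec, X0, opt = optimizer_spec(),
                                 seed = NA_integer_) {
  t_start <- proc.time()[["elapsed"]]
  delta <- as_delta_matrix(delta)
  if (spec$name != "kruskal1") {
    stop("linear_iteration is defined for the kruskal1 stress", call. = FALSE)
  }
  X <- as.matrix(X0)
  dscale <- mean(delta[upper_mask(nrow(delta))])
  if (dscale == 0) stop("degenerate input: all dissimilarities zero",
                        call. = FALSE)
  eta_eff <- opt$eta * dscale^2
  d <- embedded_distances(X)
  trace <- stress_kruskal1(delta, d)
  s_init <- trace[1]
  sweeps <- 0L
  scale_cap <- 5 * max(delta)
  for (s in seq_len(opt$max_sweeps)) {
    X <- X - eta_eff * stress_gradient(spec, delta, X)
    d <- embedded_distances(X)
    s_now <- stress_kruskal1(delta, d)
    spread <- max(apply(X, 2L, function(v) diff(range(v))))
    if (!all(is.finite(X)) || !is.finite(s_now) || spread > scale_cap ||
        s_now > 1e6 * max(s_init, 1e-12)) {
      stop("linear iteration diverged; use a smaller fixed step `eta`",
           call. = FALSE)
    }
    trace <- c(trace, s_now)
    sweeps <- s
    if (trace_converged(trace, opt$tol, opt$tol_sweeps)) break
  }
  new_embedding(X, "kruskal1", "linear_iteration", seed,
                trace[length(trace)],
                proc.time()[["elapsed"]] - t_start, trace, sweeps,
                converged = sweeps < opt$max_sweeps)
}

## ---- common driver ---------------------------------------------------------

# Run one seeded restart of an admissible pairing.
run_one <- function(delta, stress_name, optimizer_name, p, seed,
                    spec = NULL, opt = optimizer_spec(), X0 = NULL) {
  assert_admissible(stress_name, optimizer_name)
  delta <- as_delta_matrix(delta)
  if (is.null(spec)) spec <- stress_spec(stress_name)
  if (spec$name != stress_name) stop("stress spec does not match", call. = FALSE)
  if (is.null(X0)) X0 <- initialize_embedding(delta, p, seed)
  fn <- switch(optimizer_name,
    majorization = run_majorization,
    gauss_seidel_newton = run_gauss_seidel_newton,
    sgd = run_sgd,
    mcmc = run_mcmc,
    linear_iteration = run_linear_iteration
  )
  fn(delta, spec, X0, opt = opt, seed = seed)
}

#' Multi-restart embedding driver
#'
#' Runs an admissible stress/optimizer pairing `n_restarts` times from
#' different seeded initial configurations (the standard protocol is 10
#' restarts) and reports the per-run final stresses with their mean and
#' standard error, plus the best run.  NLDR is non-convex; restarts
#' measure how much the result varies with initial conditions.
#'
#' @param delta Dissimilarity matrix or `"rf_dist"`.
#' @param stress_name,optimizer_name An admissible pairing
#'   (see [admissible_pairs()]).
#' @param p Target dimension (2 or 3 for visualization).
#' @param n_restarts Number of independent restarts (default 10).
#' @param base_seed Integer; per-restart seeds are derived from it.
#' @param spec,opt Optional `"stress_spec"` / `"optimizer_spec"`.
#' @return Object of class `"run_batch"`: list with `runs` (embeddings),
#'   `final_stresses`, `mean_stress`, `se_stress`, `best` (index) and the
#'   pairing metadata.
#' @export
run_batch <- function(delta, stress_name, optimizer_name, p = 3L,
                      n_restarts = 10L, base_seed = 1L,
                      spec = NULL, opt = optimizer_spec()) {
  assert_admissible(stress_name, optimizer_name)
  delta <- as_delta_matrix(delta)
  seeds <- vapply(seq_len(n_restarts), function(r) derive_seed(base_seed, r),
                  integer(1))
  runs <- lapply(seeds, function(s) {
    run_one(delta, stress_name, optimizer_name, p, s, spec = spec, opt = opt)
  })
  fs <- vapply(runs, function(e) e$final_stress, numeric(1))
  structure(
    list(runs = runs, final_stresses = fs, mean_stress = mean(fs),
         se_stress = stats::sd(fs) / sqrt(length(fs)),
         best = which.min(fs), seeds = seeds,
         stress_name = stress_name, optimizer_name = optimizer_name, p = p),
    class = "run_batch"
  )
}

#' @export
print.run_batch <- function(x, ...) {
  cat(sprintf(
    "run_batch: %s + %s, p = %d, %d restarts\n  stress mean %.6g (se %.2g), best %.6g (run %d)\n",
    x$stress_name, x$optimizer_name, x$p, length(x$runs), x$mean_stress,
    x$se_stress, min(x$final_stresses), x$best
  ))
  invisible(x)
}
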
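# Brute-force trustworthiness for tiny instances: enumerate neighborhoods
# directly from the definition.
brute_trustworthiness <- function(delta, X, k) {
  n <- nrow(delta)
  d_emb <- as.matrix(dist(X))
  rank_in <- function(m, i, j) {
    others <- setdiff(seq_len(n), i)
    o <- others[order(m[i, others], others)]
    which(o == j)
  }
  total <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    near_emb <- others[order(d_emb[i, others], others)][seq_len(k)]
    near_del <- others[order(delta[i, others], others)][seq_len(k)]
    for (j in setdiff(near_emb, near_del)) {
      total <- total + rank_in(delta, i, j) - k
    }
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}

test_that("trustworthiness and continuity are 1 for rank-preserving embeddings", {
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  delta <- as.matrix(dist(X))
  for (k in c(1, 3, 5)) {
    expect_equal(trustworthiness(delta, X, k), 1.0)
    expect_equal(continuity(delta, X, k), 1.0)
  }
  # any monotone transform of the distances preserves ranks
  expect_equal(trustworthiness(delta^2, X, 5), 1.0)
})

test_that("N=4, k=1 toys match brute-force rank enumeration", {
  # delta puts 2 nearest to 1, but the embedding puts 3 nearest to 1
  delta <- matrix(c(0, 1, 2, 3,
                    1, 0, 2, 3,
                    2, 2, 0, 1,
                    3, 3, 1, 0), 4, 4)
  X <- cbind(c(0, 2, 0.5, 4), c(0, 0, 0, 0))
  expect_equal(trustworthiness(delta, X, 1),
               brute_trustworthiness(delta, X, 1))
  # brute continuity: swap the roles of the two spaces
  brute_continuity <- function(delta, X, k) {
    n <- nrow(delta)
    d_emb <- as.matrix(dist(X))
    total <- 0
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      o_emb <- others[order(d_emb[i, others], others)]
      near_emb <- o_emb[seq_len(k)]
      near_del <- others[order(delta[i, others], others)][seq_len(k)]
      for (j in setdiff(near_del, near_emb)) {
        total <- total + which(o_emb == j) - k
      }
    }
    1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
  }
  expect_equal(continuity(delta, X, 1), brute_continuity(delta, X, 1))
  set.seed(2)
  for (rep in 1:5) {
    d4 <- as.matrix(dist(matrix(runif(8), 4)))
    X4 <- matrix(runif(8), 4)
    expect_equal(trustworthiness(d4, X4, 1),
                 brute_trustworthiness(d4, X4, 1))
    expect_equal(continuity(d4, X4, 1), brute_continuity(d4, X4, 1))
  }
})

test_that("trustworthiness and continuity are mirror images", {
  set.seed(3)
  for (rep in 1:4) {
    X1 <- matrix(rnorm(30), 15, 2)
    X2 <- matrix(rnorm(30), 15, 2)
    D1 <- as.matrix(dist(X1))
    expect_equal(trustworthiness(D1, X2, 4),
                 continuity(as.matrix(dist(X2)), X1, 4))
  }
})

test_that("both measures degrade under progressive rank corruption", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  delta <- as.matrix(dist(X))
  corrupt <- function(frac, seed) {
    set.seed(seed)
    Y <- X
    idx <- sample(30, round(frac * 30))
    Y[idx, ] <- matrix(rnorm(length(idx) * 2, sd = 3), length(idx))
    Y
  }
  tw <- vapply(c(0, 0.3, 1), function(f) {
    mean(vapply(1:3, function(s) trustworthiness(delta, corrupt(f, s), 5),
                numeric(1)))
  }, numeric(1))
  ct <- vapply(c(0, 0.3, 1), function(f) {
    mean(vapply(1:3, function(s) continuity(delta, corrupt(f, s), 5),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(tw) < 0))
  expect_true(all(diff(ct) < 0))
  expect_equal(tw[1], 1)
})

test_that("one_nn scores label agreement in either space", {
  set.seed(5)
  A <- matrix(rnorm(40, mean = 0, sd = 0.2), 20, 2)
  B <- matrix(rnorm(40, mean = 5, sd = 0.2), 20, 2)
  X <- rbind(A, B)
  labels <- rep(c("a", "b"), each = 20)
  expect_equal(one_nn(X, labels), 1.0)
  expect_equal(one_nn(as.matrix(dist(X)), labels), 1.0)
  # random labels over L equal groups: expected agreement about 1/L
  set.seed(6)
  n <- 600
  Xr <- matrix(runif(2 * n), n, 2)
  lr <- sample(rep(c("x", "y", "z"), each = n / 3))
  agree <- one_nn(Xr, lr)
  expect_gt(agree, 1 / 3 - 0.08)
  expect_lt(agree, 1 / 3 + 0.08)
  expect_error(one_nn(X, rep("only", 40)), "single label")
})

test_that("procrustes residual vanishes for similarity copies incl. mirrors", {
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  th <- 0.8
  Q <- diag(3); Q[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 3 * X %*% Q + matrix(rep(c(1, -2, 0.5), each = 10), 10)
  expect_lt(procrustes(X, Y)$residual, 1e-10)
  Ym <- X; Ym[, 2] <- -Ym[, 2]
  expect_lt(procrustes(X, Ym)$residual, 1e-10)
  expect_error(procrustes(X, matrix(1, 10, 3)), "coincident")
})

test_that("procrustes matches a grid-search oracle and vegan on 2D", {
  set.seed(8)
  X <- matrix(rnorm(16), 8, 2)
  Y <- X; Y[4, ] <- Y[4, ] + c(0.8, -0.5)
  mine <- procrustes(X, Y)$residual
  # oracle: exhaustive rotation/reflection grid with per-angle optimal scale
  A0 <- sweep(X, 2, colMeans(X)); B0 <- sweep(Y, 2, colMeans(Y))
  ssA <- sum(A0^2)
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = 7200)) {
    for (refl in c(1, -1)) {
      R <- matrix(c(cos(th), sin(th) * refl, -sin(th), cos(th) * refl), 2)
      BR <- B0 %*% R
      s <- sum(A0 * BR) / sum(BR^2)
      best <- min(best, sum((A0 - s * BR)^2) / ssA)
    }
  }
  expect_equal(mine, best, tolerance = 1e-4)
  skip_if_not_installed("vegan")
  vp <- vegan::procrustes(X, Y, symmetric = TRUE)
  expect_equal(mine, vp$ss, tolerance = 1e-8)
})

test_that("procrustes residual is symmetric after normalization", {
  set.seed(9)
  X <- matrix(rnorm(20), 10, 2)
  Y <- matrix(rnorm(20), 10, 2)
  norm_cfg <- function(Z) {
    Z0 <- sweep(Z, 2, colMeans(Z))
    Z0 / sqrt(sum(Z0^2))
  }
  expect_equal(procrustes(norm_cfg(X), norm_cfg(Y))$residual,
               procrustes(norm_cfg(Y), norm_cfg(X))$residual,
               tolerance = 1e-10)
})

test_that("equivalence classes isolate a discordant replicate", {
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  ident <- lapply(1:10, function(i) X)
  eq0 <- equivalence_classes(ident)
  expect_equal(eq0$classes, rep(1L, 10))
  runs <- c(lapply(1:9, function(i) X + matrix(rnorm(60, sd = 0.01), 20, 3)),
            list(matrix(rnorm(60), 20, 3)))
  eq <- equivalence_classes(runs)
  expect_equal(sum(eq$classes == 1L), 9L)
  expect_equal(eq$outliers, 10L)
  expect_warning(eq2 <- equivalence_classes(runs[1:2]), "2 runs")
  expect_equal(eq2$classes, c(1L, 1L))
})

test_that("fit_report collects the diagnostics", {
  set.seed(11)
  X <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
             matrix(rnorm(30, 4, 0.2), 15, 2))
  delta <- as.matrix(dist(X))
  rep <- fit_report(delta, X, rep(c("a", "b"), each = 15), ks = c(1, 5))
  expect_equal(rep$one_nn, 1)
  expect_equal(unname(rep$trustworthiness["k5"]), 1)
  expect_equal(unname(rep$continuity["k1"]), 1)
})
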
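test_that("variance pruning removes a planted outlier and is idempotent", {
  set.seed(2)
  pts <- rbind(matrix(runif(600), 300, 2), c(100, 100))
  pr <- prune_outliers(pts, tau = 0.01)
  expect_equal(pr$removed, 301L)
  expect_false(pr$degenerate)
  again <- prune_outliers(pts[pr$retained, ], tau = 0.01)
  expect_length(again$removed, 0L)
  # under the absolute reading the tight 20-point cluster story holds too
  set.seed(3)
  pts20 <- rbind(matrix(runif(40, 0, 0.3), 20, 2), c(100, 100))
  pra <- prune_outliers(pts20, tau = 0.01, absolute = TRUE)
  expect_equal(pra$removed, 21L)
  expect_length(prune_outliers(pts20[pra$retained, ], tau = 0.01,
                               absolute = TRUE)$removed, 0L)
})

test_that("tau = 1 removes nothing; coincident points are a no-op", {
  set.seed(4)
  for (rep in 1:5) {
    pts <- matrix(rnorm(40 + 4 * rep), ncol = 2)
    expect_length(prune_outliers(pts, tau = 1.0)$removed, 0L)
  }
  same <- matrix(1, 10, 2)
  pr <- prune_outliers(same, tau = 0.01)
  expect_length(pr$removed, 0L)
})

test_that("removal never lifts the variance above its pre-removal value", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(8, 12, 1), 4, 2))
  pr <- prune_outliers(pts, tau = 0.05)
  active <- seq_len(nrow(pts))
  for (q in pr$removed) {
    v_before <- phyloscape:::spread_variance(pts[active, , drop = FALSE])
    active <- setdiff(active, q)
    v_after <- phyloscape:::spread_variance(pts[active, , drop = FALSE])
    expect_lte(v_after, v_before)
  }
})

test_that("2D hulls: square corners are vertices, center interior", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convex_hull(sq)
  expect_setequal(h$vertices, 1:4)
  expect_false(h$degenerate)
  col <- convex_hull(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_true(col$degenerate)
  expect_equal(col$dim, 1L)
  expect_setequal(col$vertices, c(1L, 3L))
})

test_that("3D hull of the cube has 8 vertices and 12 triangular facets", {
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  h <- convex_hull(cube)
  expect_setequal(h$vertices, 1:8)
  expect_equal(nrow(h$facets), 12L)
  expect_equal(ncol(h$facets), 3L)
  # every facet's outward normal leaves all points on the inner side
  ctr <- colMeans(cube)
  for (f in seq_len(nrow(h$facets))) {
    tri <- cube[h$facets[f, ], ]
    nrm <- c(
      (tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
        (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
      (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
        (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
      (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
        (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1])
    )
    if (sum(nrm * (ctr - tri[1, ])) > 0) nrm <- -nrm
    expect_true(all(sweep(cube, 2, tri[1, ]) %*% nrm <= 1e-6))
  }
  # random interior points never become hull vertices
  set.seed(6)
  inner <- matrix(runif(30, 0.2, 0.8), 10, 3)
  h2 <- convex_hull(rbind(cube, inner))
  expect_setequal(h2$vertices, 1:8)
  # coplanar 3D input falls back to a flagged planar hull
  flat <- cbind(matrix(runif(20), 10, 2), 0)
  h3 <- convex_hull(flat)
  expect_true(h3$degenerate)
  expect_equal(h3$dim, 2L)
})

test_that("hull_summary prunes per group and separate_hulls is rigid", {
  set.seed(7)
  A <- matrix(rnorm(300, -1, 0.1), 150, 2)
  B <- matrix(rnorm(300, 1, 0.1), 150, 2)
  X <- rbind(A, B, c(50, 50))
  labels <- c(rep("a", 150), rep("b", 151))
  # leave-one-out variance drops in a Gaussian cluster of this size sit
  # around a few percent, so a 20% threshold isolates the planted outlier
  hs <- hull_summary(X, labels, tau = 0.2)
  expect_equal(hs$groups$b$removed, 301L)
  expect_equal(length(hs$groups$a$removed), 0L)

  hs0 <- separate_hulls(hs, 0)
  expect_identical(hs0$groups$a$points, hs$groups$a$points)
  hs2 <- separate_hulls(hs, 2)
  # rigid translation: within-group distances preserved to rounding error
  expect_equal(as.numeric(dist(hs2$groups$a$points)),
               as.numeric(dist(hs$groups$a$points)), tolerance = 1e-12)
  # reversible
  back <- separate_hulls(hs2, -2)
  expect_equal(back$groups$a$points, hs$groups$a$points, tolerance = 1e-12)
  # centroids move by s along the global-center ray
  dir <- hs$groups$a$centroid - hs$global_centroid
  dir <- dir / sqrt(sum(dir^2))
  expect_equal(hs2$groups$a$centroid - hs$groups$a$centroid, 2 * dir,
               tolerance = 1e-12)
})

test_that("two groups on the x-axis separate to +/-3 at s = 2", {
  X <- rbind(cbind(rnorm(20, -1, 0.01), rnorm(20, 0, 0.01)),
             cbind(rnorm(20, 1, 0.01), rnorm(20, 0, 0.01)))
  hs <- hull_summary(X, rep(c("l", "r"), each = 20), tau = 1)
  hs2 <- separate_hulls(hs, 2)
  expect_equal(hs2$groups$l$centroid[1], hs$groups$l$centroid[1] - 2,
               tolerance = 0.05)
  expect_equal(hs2$groups$r$centroid[1], hs$groups$r$centroid[1] + 2,
               tolerance = 0.05)
  # single group: no defined direction, never translated
  hs1 <- hull_summary(X, rep("all", 40), tau = 1)
  hs1s <- separate_hulls(hs1, 5)
  expect_identical(hs1s$groups$all$points, hs1$groups$all$points)
})

test_that("matched landscapes share hull-centroid geometry; shuffled ones do not", {
  set.seed(8)
  centers <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0), c(2, 2, 3))
  make_landscape <- function(seed) {
    set.seed(seed)
    X <- do.call(rbind, lapply(1:4, function(g) {
      sweep(matrix(rnorm(90, 0, 0.2), 30, 3), 2, centers[g, ], `+`)
    }))
    hull_summary(X, rep(paste0("g", 1:4), each = 30), tau = 1)
  }
  h1 <- make_landscape(1)
  h2 <- make_landscape(2)
  cents <- function(h, ord = 1:4) {
    do.call(rbind, lapply(paste0("g", ord), function(g) h$groups[[g]]$centroid))
  }
  matched <- procrustes(cents(h1), cents(h2))$residual
  perms <- list(c(2, 1, 3, 4), c(1, 3, 2, 4), c(4, 2, 3, 1),
                c(2, 3, 4, 1), c(3, 4, 1, 2), c(4, 3, 2, 1))
  shuffled <- vapply(perms, function(p) {
    procrustes(cents(h1), cents(h2, p))$residual
  }, numeric(1))
  expect_lt(matched, min(shuffled))
})
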
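test_that("admissible_pairs enforces the 14-pair matrix", {
  ap <- admissible_pairs()
  expect_equal(nrow(ap), 14L)
  has <- function(s, o) any(ap$stress == s & ap$optimizer == o)
  expect_false(has("cca", "majorization"))
  expect_false(has("cca", "gauss_seidel_newton"))
  expect_true(has("kruskal1", "linear_iteration"))
  expect_false(has("kruskal1", "sgd"))
  expect_true(has("cca", "sgd"))
  expect_true(has("cca", "mcmc"))
  expect_error(run_batch(diag(0, 4) + 1 - diag(4), "cca", "majorization",
                         p = 2, n_restarts = 2),
               "admissible")
})

test_that("initialize_embedding is seeded and bounded by max delta", {
  delta <- embeddable_delta(20)$delta
  X1 <- initialize_embedding(delta, 3, 42)
  X2 <- initialize_embedding(delta, 3, 42)
  X3 <- initialize_embedding(delta, 3, 43)
  expect_identical(X1, X2)
  expect_false(identical(X1, X3))
  expect_true(all(X1 >= 0 & X1 <= max(delta)))
  expect_equal(dim(X1), c(20L, 3L))
})

test_that("majorization descends monotonically and recovers geometry", {
  inst <- embeddable_delta(30, p = 2, seed = 3)
  emb <- run_majorization(inst$delta, stress_spec("normalized"),
                          initialize_embedding(inst$delta, 2, 5))
  expect_true(all(diff(emb$trace) <= 1e-12))
  expect_lt(emb$final_stress, 1e-4)
  # 4 corners of the unit square are recovered up to similarity
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  emb2 <- run_majorization(as.matrix(dist(sq)), stress_spec("normalized"),
                           initialize_embedding(as.matrix(dist(sq)), 2, 2))
  expect_lt(procrustes(sq, emb2$X)$residual, 1e-3)
  expect_error(run_majorization(matrix(0, 4, 4), stress_spec("normalized"),
                                matrix(rnorm(8), 4, 2)), "zero")
})

test_that("gauss_seidel_newton converges and its point update is optimal", {
  inst <- embeddable_delta(25, p = 2, seed = 8)
  emb <- run_gauss_seidel_newton(inst$delta, stress_spec("normalized"),
                                 initialize_embedding(inst$delta, 2, 4))
  expect_lt(emb$final_stress, 1e-4)
  maj <- run_majorization(inst$delta, stress_spec("normalized"),
                          initialize_embedding(inst$delta, 2, 4))
  expect_lt(emb$final_stress, max(maj$final_stress * 1.05, 1e-4))

  # freezing all points but one: repeated per-point updates reach the
  # brute-force optimum of that point's restricted stress
  set.seed(6)
  delta <- embeddable_delta(8, p = 2, seed = 9)$delta
  X <- embeddable_delta(8, p = 2, seed = 9)$points
  X[3, ] <- X[3, ] + c(0.4, -0.3)  # displace one point
  st <- phyloscape:::make_point_state("normalized", delta, X)
  for (it in 1:50) phyloscape:::gsn_update_point(st, 3L)
  restricted <- function(xy) {
    X2 <- X; X2[3, ] <- xy
    stress_normalized(delta, embedded_distances(X2))
  }
  opt <- stats::optim(X[3, ], restricted, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(phyloscape:::point_state_stress(st), opt$value,
               tolerance = 1e-3)
})

test_that("sgd recovers exactly-embeddable instances and is reproducible", {
  inst <- embeddable_delta(30, p = 2, seed = 12)
  e1 <- run_sgd(inst$delta, stress_spec("normalized"),
                initialize_embedding(inst$delta, 2, 21), seed = 21)
  expect_lt(e1$final_stress, 1e-3)
  e2 <- run_sgd(inst$delta, stress_spec("normalized"),
                initialize_embedding(inst$delta, 2, 21), seed = 21)
  expect_identical(e1$X, e2$X)
  e3 <- run_sgd(inst$delta, stress_spec("cca"),
                initialize_embedding(inst$delta, 2, 21), seed = 21)
  expect_lt(e3$final_stress, 1e-3)
})

test_that("mcmc anneals: acceptance sane, best state returned", {
  inst <- embeddable_delta(10, p = 2, seed = 14)
  opt <- optimizer_spec(max_sweeps = 400)
  emb <- run_mcmc(inst$delta, stress_spec("normalized"),
                  initialize_embedding(inst$delta, 2, 3), opt = opt,
                  seed = 3)
  expect_gt(emb$acceptance_rate, 0)
  expect_lt(emb$acceptance_rate, 1)
  expect_lt(emb$final_stress, 1e-2)
  expect_lte(emb$final_stress, min(emb$trace) + 1e-15)
  emb2 <- run_mcmc(inst$delta, stress_spec("normalized"),
                   initialize_embedding(inst$delta, 2, 3), opt = opt,
                   seed = 3)
  expect_identical(emb$X, emb2$X)
})

test_that("linear iteration descends with the default step, diverges with an absurd one", {
  inst <- embeddable_delta(50, p = 2, seed = 7)
  X0 <- initialize_embedding(inst$delta, 2, 11)
  emb <- run_linear_iteration(inst$delta, stress_spec("kruskal1"), X0)
  expect_lt(emb$final_stress, 1e-2)
  expect_error(
    run_linear_iteration(inst$delta, stress_spec("kruskal1"), X0,
                         opt = optimizer_spec(eta = 100)),
    "smaller fixed step"
  )
  expect_error(run_linear_iteration(inst$delta, stress_spec("normalized"),
                                    X0), "kruskal1")
})

test_that("fixed-step descent is not monotone somewhere on random instances", {
  upticks <- 0L
  for (s in 1:5) {
    delta <- as.matrix(dist(matrix(stats::rnorm(40, sd = s), 20, 2)))
    emb <- tryCatch(
      run_linear_iteration(delta, stress_spec("kruskal1"),
                           initialize_embedding(delta, 2, s),
                           opt = optimizer_spec(max_sweeps = 200, eta = 2)),
      error = function(e) NULL
    )
    if (!is.null(emb) && any(diff(emb$trace) > 0)) upticks <- upticks + 1L
  }
  expect_gt(upticks, 0L)
})

test_that("run_batch runs seeded restarts and summarizes them", {
  inst <- embeddable_delta(15, p = 2, seed = 18)
  b <- run_batch(inst$delta, "normalized", "majorization", p = 2,
                 n_restarts = 4, base_seed = 9)
  expect_length(b$runs, 4L)
  expect_length(unique(b$seeds), 4L)
  expect_equal(min(b$final_stresses), b$final_stresses[b$best])
  expect_true(all(min(b$final_stresses) <= b$final_stresses))
  expect_equal(b$mean_stress, mean(b$final_stresses))
  # final <= initial stress on every restart
  for (r in b$runs) expect_lte(r$final_stress, r$trace[1] + 1e-12)
})
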
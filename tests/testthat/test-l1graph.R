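test_that("re-weighting divides by twice the floored profile distance", {
  W <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  Q <- rbind(c(0.3, 0), c(0, 0))  # row distance 0.3
  Wt <- reweight(W, Q, epsilon = 1e-8)
  expect_equal(Wt[1, 2], 1.0)
  expect_equal(Wt[2, 1], 1.0)

  # zero weight stays zero whatever the profiles
  expect_equal(reweight(matrix(0, 2, 2), Q)[1, 2], 0)

  # identical rows hit the epsilon floor
  Qsame <- rbind(c(1, 1), c(1, 1))
  expect_equal(reweight(W, Qsame, epsilon = 1e-4)[1, 2], 0.6 / (2e-4))

  # diagonal forced to zero even though self-distance is floored
  Wd <- matrix(1, 2, 2)
  expect_equal(diag(reweight(Wd, Q)), c(0, 0))

  expect_error(reweight(W, rbind(Q, Q)), "rows")
})

test_that("the objective combines smoothness and anchored fidelity", {
  toy <- toy_instance()
  # at Q = A the fidelity term vanishes
  dists <- as.matrix(dist(toy$A))
  expect_equal(graph_objective(toy$W, toy$A, toy$A, 1), sum(toy$W * dists))
  # zero graph, unit shift, U = I: one squared unit residual per cell
  k <- 3; c <- 4
  A <- matrix(0, k, c)
  expect_equal(graph_objective(matrix(0, k, k), A + 1, A, 1), k * c)
  # single row: no pairs, only the anchored residual
  expect_equal(graph_objective(matrix(0, 1, 1), matrix(2, 1, 2),
                               matrix(0, 1, 2), 3), 3 * 8)
})

test_that("a zero graph returns the anchors exactly", {
  A <- rbind(c(1, 0), c(0, 1), c(1, 1))
  sol <- solve_space(matrix(0, 3, 3), A)
  expect_equal(unname(sol$Q), A, tolerance = 1e-12)
  expect_true(sol$converged)
  expect_equal(sol$iterations, 1L)
})

test_that("a dominant anchor pins the solution to the associations", {
  toy <- toy_instance()
  residuals <- vapply(c(1, 1e2, 1e4, 1e8), function(aw) {
    sol <- solve_space(toy$W, toy$A, solver_config(anchor_weight = aw))
    sqrt(sum((sol$Q - toy$A)^2))
  }, numeric(1))
  expect_true(all(diff(residuals) < 0))   # strictly decreasing in anchor weight
  expect_lt(residuals[4], 1e-6)
})

test_that("the objective trace is non-increasing on random problems", {
  for (seed in 1:12) {
    prob <- random_problem(n = 6, m = 4, seed = seed)
    sol <- solve_space(prob$W_m, prob$A, solver_config(max_iter = 60))
    expect_true(all(diff(objective_trace(sol)) <= 1e-10),
                info = sprintf("seed %d", seed))
  }
})

test_that("the converged objective matches brute-force minimization", {
  cfg <- solver_config(tol = 1e-12, max_iter = 3000)
  # the spec toy plus small random instances up to 5 x 3
  toy <- toy_instance()
  cases <- list(list(W = toy$W, A = toy$A))
  for (seed in 1:3) {
    prob <- random_problem(n = sample(3:5, 1), m = sample(2:3, 1), seed = seed + 40)
    W <- prob$W_m; diag(W) <- 0
    cases[[length(cases) + 1L]] <- list(W = W, A = prob$A)
  }
  for (cs in cases) {
    sol <- solve_space(cs$W, cs$A, cfg)
    ours <- utils::tail(objective_trace(sol), 1)
    oracle <- brute_min_objective(cs$W, cs$A, 1)
    expect_lt(abs(ours - oracle), 1e-4)
  }
})

test_that("fusion averages the two space solutions and keeps labels", {
  prob <- random_problem(n = 5, m = 4, seed = 99)
  fit <- l1graph(prob$A, prob$W_m, prob$W_d)
  sm <- solve_space(prob$W_m, prob$A, fit$config)
  sd_ <- solve_space(prob$W_d, t(prob$A), fit$config)
  expect_equal(fit$scores, (sm$Q + t(sd_$Q)) / 2, tolerance = 1e-10)
  expect_identical(dimnames(fit$scores), dimnames(prob$A))

  # both graphs zero: the fused output is the input associations
  Wm0 <- toy_similarity(5, rownames(prob$A)); Wd0 <- toy_similarity(4, colnames(prob$A))
  fit0 <- l1graph(prob$A, Wm0, Wd0)
  # identity similarity has zero off-diagonal weight; reweight zeroes the diagonal
  expect_equal(unname(fit0$scores), unname(prob$A), tolerance = 1e-12)
})

test_that("label mismatches are rejected with the missing entities named", {
  prob <- random_problem(n = 4, m = 3, seed = 3)
  Wm_bad <- prob$W_m
  rownames(Wm_bad) <- colnames(Wm_bad) <- c("M01", "M02", "M03", "ZZZ")
  expect_error(l1graph(prob$A, Wm_bad, prob$W_d), "M04")
})

test_that("permuting miRNA order permutes the fused scores identically", {
  prob <- random_problem(n = 6, m = 4, seed = 17)
  fit <- l1graph(prob$A, prob$W_m, prob$W_d)
  perm <- c(4, 1, 6, 2, 5, 3)
  fit_p <- l1graph(prob$A[perm, ], prob$W_m[perm, perm], prob$W_d)
  expect_equal(fit_p$scores, fit$scores[perm, ], tolerance = 1e-9)
})

test_that("scaling the similarity matrix keeps the solver well-behaved", {
  prob <- random_problem(n = 5, m = 3, seed = 23)
  for (lambda in c(0.1, 1, 10)) {
    sol <- solve_space(lambda * prob$W_m, prob$A, solver_config(max_iter = 60))
    expect_true(all(is.finite(sol$Q)))
    expect_true(all(diff(objective_trace(sol)) <= 1e-10))
    # Laplacian row sums vanish (relative to the degree scale: the epsilon
    # floor can make re-weighted degrees very large)
    expect_lt(max(abs(rowSums(sol$L_tilde))) / max(1, sol$D_tilde), 1e-12)
    expect_true(all(sol$W_tilde >= 0))
    expect_equal(unname(diag(sol$W_tilde)), rep(0, 5))
  }
})

test_that("the model object exposes the standard methods", {
  fx <- make_fixture(fixture_spec(seed = 4))
  fit <- l1graph(fx$A, fx$W_m, fx$W_d)
  expect_s3_class(fit, "l1graph")
  expect_identical(coef(fit), fit$scores)
  expect_identical(fitted(fit), fit$scores)
  expect_equal(residuals(fit), fit$scores - fx$A)
  expect_output(print(fit), "association model")
  expect_output(print(summary(fit)), "final objectives")
  ranked <- predict(fit, disease = colnames(fx$A)[2], k = 5)
  expect_s3_class(ranked, "ranked_candidates")
  expect_equal(nrow(ranked), 5L)
  expect_identical(predict(fit), fit$scores)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
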
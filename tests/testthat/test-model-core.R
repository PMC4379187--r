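test_that("expected adjacency is the symmetric outer product", {
  expect_equal(expected_adjacency(matrix(0, 3, 2)), matrix(0, 3, 3))
  expect_equal(expected_adjacency(matrix(1, 3, 1)), matrix(1, 3, 3))
  expect_equal(expected_adjacency(diag(c(1, 2))), diag(c(1, 4)))
})

test_that("l2,1 norm sums column norms", {
  expect_equal(l21_norm(matrix(0, 4, 3)), 0)
  expect_equal(l21_norm(diag(2)), 2)
  expect_equal(l21_norm(matrix(c(3, 4), 2, 1)), 5)
})

test_that("objective decomposes into error and penalty terms", {
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(objective_loss(a, matrix(0, 2, 1), 1)$loss, sum(a^2))
  u <- matrix(c(3, 4), 2, 1)
  expect_equal(objective_loss(expected_adjacency(u), u, 0)$loss, 0)
  # hand evaluation: A = [[0,1],[1,0]], U = (1,1)': UU' = ones, error = 2,
  # penalty = 2*sqrt(2)
  ob <- objective_loss(a, matrix(1, 2, 1), 2)
  expect_equal(ob$error_term, 2)
  expect_equal(ob$reg_term, 2 * sqrt(2))
  expect_equal(ob$loss, 2 + 2 * sqrt(2))
  expect_error(objective_loss(a, matrix(1, 3, 1), 1), "dimension")
})

test_that("trace-based loss equals the dense evaluation", {
  set.seed(4)
  A <- random_graph(10, 0.4)
  U <- matrix(runif(10 * 3), 10, 3)
  ob <- objective_loss(A, U, 1.3)
  expect_equal(ob$loss, loss_direct(A, U, 1.3), tolerance = 1e-10)
})

test_that("gradient matches the scalar case and finite differences", {
  expect_equal(membership_gradient(matrix(2, 1, 1), matrix(1, 1, 1), 0),
               matrix(-4, 1, 1))
  set.seed(11)
  A <- random_graph(6, 0.5)
  U <- matrix(runif(6 * 3, 0.2, 1), 6, 3)
  for (lam in c(0, 0.7, 2.5)) {
    g <- membership_gradient(A, U, lam)
    fd <- fd_gradient(A, U, lam)
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
  }
  expect_error(membership_gradient(A, cbind(U, 0), 1), "zero")
})

test_that("stationarity of the fixed-point relation nulls gradient * U", {
  # run a fit deep enough that the multiplicative fixed point holds, then
  # check complementary slackness entrywise
  set.seed(2)
  A <- two_cliques(4)
  fit <- snmf_fit(A, k_init = 2, lambda = 0.5, n_restarts = 3, seed = 8,
                  rel_tol = 1e-12, max_iter = 30000)
  U <- fit$membership
  keep <- sqrt(colSums(U^2)) > 0
  g <- membership_gradient(A, U[, keep, drop = FALSE] + 0, 0.5)
  expect_lt(max(abs(g * U[, keep])), 1e-5 * sum(A^2))
})

test_that("multiplicative update preserves nonnegativity and zero entries", {
  expect_equal(update_step(matrix(0, 3, 3), matrix(runif(6), 3, 2), 1),
               matrix(0, 3, 2))
  set.seed(3)
  A <- random_graph(8, 0.4)
  U <- matrix(runif(8 * 3), 8, 3)
  U[, 2] <- 0
  up <- update_step(A, U, 1.5)
  expect_true(all(up >= 0))
  expect_equal(up[, 2], rep(0, 8))
  # exact factorization of a scalar is a fixed point
  expect_equal(update_step(matrix(1, 1, 1), matrix(1, 1, 1), 0),
               matrix(1, 1, 1), tolerance = 1e-9)
  # nonnegativity over randomized trials
  for (i in 1:20) {
    A <- random_graph(7, 0.5)
    U <- matrix(runif(7 * 4), 7, 4)
    expect_true(all(update_step(A, U, runif(1, 0, 5)) >= 0))
  }
})

test_that("fit returns the minimum-loss restart with consistent terms", {
  A <- two_cliques(6)
  fit <- snmf_fit(A, k_init = 4, lambda = 0.2, n_restarts = 6, seed = 3)
  expect_s3_class(fit, "gsnmf_fit")
  expect_equal(fit$loss, min(fit$restart_losses))
  expect_equal(fit$loss, fit$error_term + fit$reg_term, tolerance = 1e-8)
  expect_equal(length(fit$restart_losses), 6)
  expect_true(all(fit$membership >= 0))
  expect_error(snmf_fit(matrix(c(0, 1, 2, 0), 2, 2), 2, 1), "symmetric")
})

test_that("an empty network yields the zero matrix at zero loss", {
  fit <- snmf_fit(matrix(0, 5, 5), k_init = 3, lambda = 1, n_restarts = 2,
                  seed = 1)
  expect_equal(fit$membership, matrix(0, 5, 3))
  expect_equal(fit$loss, 0)
})

test_that("two disjoint cliques are recovered as a hard partition", {
  A <- two_cliques(6)
  fit <- snmf_fit(A, k_init = 4, lambda = 0.2, n_restarts = 10, seed = 3,
                  rel_tol = 1e-9)
  part <- hard_partition(prune_communities(fit)$membership)
  expect_equal(nmi(part, rep(1:2, each = 6)), 1)
})

test_that("loss trajectory is non-increasing within slack", {
  set.seed(6)
  A <- random_graph(15, 0.3)
  for (lam in c(0, 1, 4)) {
    fit <- snmf_fit(A, k_init = 5, lambda = lam, n_restarts = 2, seed = 21)
    tr <- fit$loss_trajectory
    expect_true(all(diff(tr) <= 1e-9 * (1 + abs(tr[-length(tr)]))))
  }
})

test_that("with no penalty an exact factorization is recovered", {
  set.seed(42)
  V <- matrix(runif(8 * 3), 8, 3)
  A <- tcrossprod(V)
  fit <- snmf_fit(A, k_init = 3, lambda = 0, n_restarts = 10, seed = 7,
                  rel_tol = 1e-13, max_iter = 50000)
  expect_lt(fit$error_term, 1e-6 * sum(A^2))
})

test_that("fits are reproducible and permutation-equivariant", {
  net <- load_fixture("karate")$network
  f1 <- snmf_fit(net, 17, 1.7, n_restarts = 3, seed = 5)
  f2 <- snmf_fit(net, 17, 1.7, n_restarts = 3, seed = 5)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$restart_losses, f2$restart_losses)

  # permuting vertices and the initializations permutes the solution
  A <- two_cliques(4)
  set.seed(9)
  inits <- lapply(1:3, function(i) matrix(runif(8 * 3), 8, 3))
  p <- sample(8)
  fa <- snmf_fit(A, 3, 0.8, n_restarts = 3, init = inits)
  fb <- snmf_fit(A[p, p], 3, 0.8, n_restarts = 3,
                 init = lapply(inits, function(u) u[p, , drop = FALSE]))
  expect_equal(fb$membership, fa$membership[p, ], tolerance = 1e-8)
  expect_equal(fb$loss, fa$loss, tolerance = 1e-8)
})

test_that("KKT residual vanishes at solutions and tightens with tolerance", {
  net <- load_fixture("karate")$network
  expect_equal(kkt_residual(net, matrix(0, 34, 3), 1.7), 0)
  set.seed(13)
  U <- matrix(runif(34 * 3, 0.5, 1), 34, 3)
  expect_gt(kkt_residual(net, U, 1.7), 0)

  fit <- snmf_fit(net, 17, 1.7, n_restarts = 5, seed = 1)
  expect_lt(kkt_residual(net, fit$membership, 1.7),
            1e-4 * sum(net$adjacency^2))

  res <- vapply(c(1e-4, 1e-6, 1e-8), function(rt) {
    f <- snmf_fit(net, 17, 1.7, n_restarts = 3, seed = 11, rel_tol = rt,
                  max_iter = 20000)
    kkt_residual(net, f$membership, 1.7)
  }, 0)
  expect_true(all(diff(res) < 0))
})

test_that("tidy/glance summarize a fit", {
  net <- load_fixture("karate")$network
  fit <- snmf_fit(net, 5, 1, n_restarts = 2, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 34 * 5)
  expect_true(all(td$membership >= 0))
  gl <- glance(fit)
  expect_equal(gl$n_vertices, 34)
  expect_equal(gl$loss, fit$loss)
  expect_s3_class(autoplot(fit), "ggplot")
})
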
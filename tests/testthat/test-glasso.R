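test_that("negative log-likelihood has its closed-form values", {
  expect_equal(neg_log_likelihood(diag(3), diag(3)), 3)
  expect_equal(neg_log_likelihood(diag(c(2, 2)), diag(2)), -2 * log(2) + 4)
  expect_error(neg_log_likelihood(diag(c(1, -1)), diag(2)),
               "positive definite")
})

test_that("negative log-likelihood is minimized at the inverse covariance", {
  set.seed(2)
  S <- random_pd(4)
  O_star <- solve(S)
  v_star <- neg_log_likelihood(O_star, S)
  for (r in 1:100) {
    P <- matrix(rnorm(16, sd = 0.05), 4)
    O <- O_star + (P + t(P)) / 2
    if (min(eigen(O, symmetric = TRUE, only.values = TRUE)$values) <= 0) next
    expect_lte(v_star, neg_log_likelihood(O, S))
  }
})

test_that("penalized objective covers scalar, matrix and zero penalties", {
  expect_equal(penalized_objective(diag(2), diag(2), 0.5), 2 + 0.5 * 2)
  set.seed(3)
  S <- random_pd(3)
  O <- solve(S)
  expect_equal(penalized_objective(O, S, 0), neg_log_likelihood(O, S))
  expect_equal(penalized_objective(O, S, matrix(0.3, 3, 3)),
               penalized_objective(O, S, 0.3))
})

test_that("soft threshold matches its definition", {
  expect_equal(soft_threshold(0.7, 0.5), 0.2)
  expect_equal(soft_threshold(-0.3, 0.5), 0)
  x <- rnorm(10)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("p = 2 solution matches the closed form", {
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  fit <- graphical_lasso(S, lambda = 0.1, eps = 1e-12)
  expect_equal(fit$Sigma, matrix(c(1.1, 0.7, 0.7, 1.1), 2), tolerance = 1e-6)
  expect_equal(fit$Omega, matrix(c(1.1, -0.7, -0.7, 1.1), 2) / 0.72,
               tolerance = 1e-6)
})

test_that("diagonal input gives the diagonal closed form", {
  S <- diag(c(2, 3, 0.5))
  fit <- graphical_lasso(S, lambda = 0.2)
  expect_equal(fit$Sigma, S + 0.2 * diag(3))
  expect_equal(fit$Omega, solve(S + 0.2 * diag(3)))
})

test_that("stationarity conditions hold on randomized instances", {
  set.seed(4)
  for (r in 1:50) {
    p <- sample(3:10, 1)
    S <- random_pd(p)
    lam <- runif(1, 0.05, 0.3)
    fit <- graphical_lasso(S, lam, eps = 1e-10)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$Omega - t(fit$Omega))), 1e-8)
    expect_gt(min(eigen(fit$Omega, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    expect_lt(kkt_residual(fit$Omega, S, matrix(lam, p, p)), 1e-4)
  }
})

test_that("objective matches an independent ADMM solver", {
  set.seed(5)
  for (r in 1:50) {
    p <- sample(3:8, 1)
    S <- random_pd(p)
    lam <- runif(1, 0.05, 0.3)
    fit <- graphical_lasso(S, lam, eps = 1e-10)
    X <- admm_glasso(S, matrix(lam, p, p))
    expect_equal(penalized_objective(fit$Omega, S, lam),
                 penalized_objective(X, S, lam), tolerance = 1e-4)
  }
})

test_that("support shrinks monotonically in lambda and vanishes at lambda_max", {
  set.seed(6)
  for (r in 1:5) {
    p <- 6
    S <- random_pd(p)
    lam_max <- max(abs(S[upper.tri(S)]))
    grid <- seq(0.05 * lam_max, lam_max, length.out = 10)
    edges <- vapply(grid, function(l) count_edges(graphical_lasso(S, l)),
                    numeric(1))
    # the support path of the exact solution is not strictly nested; allow
    # single-edge blips but require a decreasing trend and an empty end
    expect_true(all(diff(edges) <= 1))
    expect_lt(sum(pmax(diff(edges), 0)), 3)
    expect_equal(edges[10], 0)
  }
})

test_that("final objective does not exceed the initialization objective", {
  set.seed(7)
  for (r in 1:10) {
    p <- sample(3:8, 1)
    S <- random_pd(p)
    lam <- runif(1, 0.05, 0.3)
    fit <- graphical_lasso(S, lam)
    O0 <- solve(S + lam * diag(p))
    expect_lte(penalized_objective(fit$Omega, S, lam),
               penalized_objective(O0, S, lam) + 1e-10)
  }
})

test_that("solver consistency: running inverse tracks the precision matrix", {
  set.seed(8)
  S <- random_pd(6)
  fit <- graphical_lasso(S, 0.1, eps = 1e-10)
  expect_lt(norm(fit$Omega %*% fit$Sigma - diag(6), "F"), 1e-3)
})

test_that("zeros are exact and the support is symmetric", {
  set.seed(9)
  S <- random_pd(8)
  fit <- graphical_lasso(S, 0.25)
  O <- fit$Omega
  expect_true(any(O[upper.tri(O)] == 0))      # some exact zeros
  expect_identical(O == 0, t(O) == 0)
})

test_that("data-frame interface equals the covariance interface", {
  set.seed(10)
  x <- as.data.frame(matrix(rnorm(200), 40, 5))
  f1 <- ggm_glasso(x, 0.1)
  f2 <- graphical_lasso(sample_covariance(x), 0.1)
  expect_identical(f1$Omega, f2$Omega)
})
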
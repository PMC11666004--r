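# Independent oracles used to cross-check the solvers. These deliberately
# use different algorithms from the implementation under test.

# random positive definite covariance with O(1) conditioning
random_pd <- function(p, jitter = 0.3) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + jitter * diag(p)
}

# ADMM solver for the element-wise L1-penalized negative log-likelihood
# (penalized diagonal). Proximal steps via eigendecomposition -- entirely
# distinct from the coordinate-descent path being tested.
admm_glasso <- function(S, Lambda, rho = 1, iters = 5000, tol = 1e-9) {
  p <- nrow(S)
  X <- diag(p); Z <- diag(p); U <- matrix(0, p, p)
  for (it in seq_len(iters)) {
    eg <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (eg$values + sqrt(eg$values^2 + 4 * rho)) / (2 * rho)
    X <- eg$vectors %*% (d * t(eg$vectors))
    Zold <- Z
    Z <- soft_threshold(X + U, Lambda / rho)
    U <- U + X - Z
    if (max(abs(X - Z)) < tol && max(abs(Z - Zold)) < tol) break
  }
  X
}

# worst-case KKT residual of the stationarity system of the penalized
# likelihood at Omega, using the exact inverse
kkt_residual <- function(Omega, S, Lambda) {
  G <- S - solve(Omega)
  p <- nrow(S)
  res <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) {
      res <- max(res, abs(G[i, i] + Lambda[i, i] * sign(Omega[i, i])))
    } else if (Omega[i, j] != 0) {
      res <- max(res, abs(G[i, j] + Lambda[i, j] * sign(Omega[i, j])))
    } else {
      res <- max(res, max(0, abs(G[i, j]) - Lambda[i, j]))
    }
  }
  res
}

# maximum-likelihood value over a fixed symmetric support (diagonal plus the
# given i<j pairs), by quasi-Newton on the free entries
support_mle <- function(S, pairs) {
  p <- nrow(S)
  pairs <- matrix(pairs, ncol = 2)
  idx <- rbind(cbind(seq_len(p), seq_len(p)), pairs)
  build <- function(th) {
    O <- matrix(0, p, p)
    for (k in seq_len(nrow(idx))) {
      O[idx[k, 1], idx[k, 2]] <- th[k]
      O[idx[k, 2], idx[k, 1]] <- th[k]
    }
    O
  }
  fn <- function(th) {
    ev <- eigen(build(th), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) return(1e10)
    -sum(log(ev)) + sum(build(th) * S)
  }
  gr <- function(th) {
    O <- build(th)
    G <- S - solve(O)
    vapply(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (i == j) G[i, i] else 2 * G[i, j]
    }, numeric(1))
  }
  stats::optim(c(1 / diag(S), rep(0, nrow(pairs))), fn, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))$value
}

# best constrained-MLE objective over every symmetric support with at most
# max_pairs off-diagonal pairs (diagonal always free)
best_support_mle <- function(S, max_pairs) {
  p <- nrow(S)
  allp <- t(utils::combn(p, 2))
  best <- Inf
  for (m in 0:max_pairs) {
    sets <- if (m == 0) list(integer(0)) else
      utils::combn(nrow(allp), m, simplify = FALSE)
    for (cmb in sets)
      best <- min(best, support_mle(S, allp[cmb, , drop = FALSE]))
  }
  best
}
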
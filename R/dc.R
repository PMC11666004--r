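#' Penalty-parameter search for the DC iteration
#'
#' Starting from the smallest eigenvalue of `S`, repeatedly shrinks
#' `eta <- alpha * eta` until `S - eta * V` is positive definite. Every
#' smallest-eigenvalue computation is counted, including the initial
#' `lambda_min(S)`, because these eigenvalue calls dominate the overhead of
#' the DC algorithm over a single graphical lasso solve and are reported in
#' the iteration diagnostics.
#'
#' @param S A `sample_covariance` or symmetric matrix with
#'   `lambda_min(S) > 0`.
#' @param V Symmetric subgradient matrix from [subgradient_matrix()].
#' @param alpha Shrinking factor in (0, 1).
#' @param pd_tolerance Positive-definiteness margin: `S - eta * V` is accepted
#'   once its smallest eigenvalue exceeds this value.
#' @param max_shrinks Cap on the number of shrink steps.
#' @return A list with `eta` (the accepted penalty parameter) and `n_eig`
#'   (number of smallest-eigenvalue computations performed).
#' @examples
#' find_eta(diag(2), diag(2), alpha = 0.5)  # eta 0.5, n_eig 2
#' @export
find_eta <- function(S, V, alpha = 0.5, pd_tolerance = 1e-10,
                     max_shrinks = 60L) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  Smat <- as_sample_covariance(S)$S
  lam_min <- function(M) min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)

  n_eig <- 1L
  lmin_S <- lam_min(Smat)
  if (lmin_S <= 0)
    stop(paste0("smallest eigenvalue of S is ", format(lmin_S),
                " <= 0; apply covariance shrinkage (shrink_covariance) ",
                "to obtain a positive definite S"), call. = FALSE)

  eta <- lmin_S
  for (k in seq_len(max_shrinks)) {
    eta <- alpha * eta
    n_eig <- n_eig + 1L
    if (lam_min(Smat - eta * V) > pd_tolerance)
      return(list(eta = eta, n_eig = n_eig))
  }
  stop("could not find eta making S - eta*V positive definite; ",
       "S is numerically singular -- apply covariance shrinkage", call. = FALSE)
}

#' DC (difference-of-convex) objective
#'
#' The penalized form of the cardinality-constrained likelihood problem:
#' \eqn{-\log\det(\Omega) + \mathrm{tr}(\Omega S) +
#' \eta(\|vec(\Omega)\|_1 - |||vec(\Omega)|||_K)}. The penalty term is
#' nonnegative and vanishes exactly when `vec(Omega)` has at most `K`
#' nonzeros.
#'
#' @inheritParams neg_log_likelihood
#' @param K Cardinality budget on `vec(Omega)` (diagonal included).
#' @param eta Positive penalty parameter.
#' @return A single number.
#' @export
dc_objective <- function(Omega, S, K, eta) {
  w <- as.vector(as.matrix(Omega))
  neg_log_likelihood(Omega, S) + eta * (sum(abs(w)) - largest_k_norm(w, K))
}

#' Convex surrogate objective of one DC iteration
#'
#' The largest-K norm in [dc_objective()] is replaced by its linearization at
#' the incumbent `Omega_t`: \eqn{g_t(\Omega) = -\log\det(\Omega) +
#' \mathrm{tr}(\Omega S) + \eta\|vec(\Omega)\|_1 -
#' \eta\langle V(\Omega_t), \Omega\rangle}, with `V` the symmetry-preserving
#' subgradient of [subgradient_matrix()]. Because every entry of `V` lies in
#' `{-1,0,1}` with at most `K` nonzeros, `g_t` majorizes the DC objective:
#' `g_t(Omega) >= dc_objective(Omega, ...)` for every `Omega`, with equality
#' at `Omega_t` whenever the diagonal-first selection attains the largest-K
#' norm there.
#'
#' @inheritParams dc_objective
#' @param Omega_t Incumbent iterate at which the concave part is linearized.
#' @param V Optional precomputed subgradient matrix for `Omega_t`.
#' @return A single number.
#' @export
surrogate_objective <- function(Omega, S, K, eta, Omega_t,
                                V = subgradient_matrix(Omega_t, K)) {
  Omega <- as.matrix(Omega)
  neg_log_likelihood(Omega, S) +
    eta * sum(abs(Omega)) - eta * sum(V * Omega)
}

#' Cardinality-constrained precision estimation by a DC algorithm
#'
#' Minimizes the DC penalty form of the L0-budgeted Gaussian likelihood.
#' Each outer iteration (i) forms the symmetry-preserving largest-K
#' subgradient `V` at the incumbent precision matrix, (ii) searches for the
#' largest penalty parameter `eta = alpha^k * lambda_min(S)` keeping
#' `S - eta * V` positive definite, and (iii) solves the convex subproblem by
#' calling [graphical_lasso()] on `S - eta * V` with scalar penalty `eta` --
#' the identical code path used for plain L1 estimation. Subproblems after
#' the first are warm-started at the incumbent iterate, so once the top-K
#' support stabilizes the solver confirms the fixed point immediately and the
#' outer loop terminates after very few iterations. Iteration stops when
#' the squared Frobenius change of the precision iterate falls below `eps`.
#'
#' @param S A `sample_covariance` or symmetric positive definite matrix.
#' @param K Cardinality budget on `vec(Omega)`, integer in `[p, p^2]`; the
#'   implied edge budget is `(K - p) / 2`.
#' @param alpha Shrinking parameter of the eta search, in (0, 1).
#' @param eps Outer convergence threshold (squared Frobenius change).
#' @param Omega0 Initial precision matrix; default `solve(S + I)`.
#' @param max_dc_iter Cap on outer DC iterations.
#' @param max_eta_shrinks Cap on shrink steps inside the eta search.
#' @param pd_tolerance Positive-definiteness margin of the eta search.
#' @param solver_eps,inner_tol,inner_max_iter,max_glasso_iter Settings for
#'   the graphical lasso subproblem solver.
#' @return An object of classes `ggm_dc`/`ggm_fit` with the fields of a
#'   [graphical_lasso()] fit plus `K`, `dc_iterations`, `n_eig` (total count
#'   of smallest-eigenvalue computations) and `trace`, a tibble with one row
#'   per outer iteration: `iteration`, `eta`, `n_eig`, `dc_objective`,
#'   `surrogate_objective`, `nnz` (nonzeros of `vec(Omega)`), `delta`
#'   (squared Frobenius step).
#' @examples
#' truth <- make_chain_graph_precision(10, seed = 1)
#' x <- sample_ggm_data(truth, n = 200, seed = 2)
#' fit <- ggm_dc(x, edges = truth$n_true_edges, zeta = 0.2)
#' fit$trace
#' @export
dc_estimate <- function(S, K, alpha = 0.5, eps = 1e-4, Omega0 = NULL,
                        max_dc_iter = 50L, max_eta_shrinks = 60L,
                        pd_tolerance = 1e-10, solver_eps = 1e-4,
                        inner_tol = 1e-6, inner_max_iter = 1000L,
                        max_glasso_iter = 200L) {
  cov <- as_sample_covariance(S)
  p <- cov$p
  if (length(K) != 1L || K != round(K) || K < p || K > p * p)
    stop(sprintf("K must be an integer in [p, p^2] = [%d, %d]", p, p * p),
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (eps <= 0) stop("`eps` must be positive", call. = FALSE)

  Omega_t <- if (is.null(Omega0)) solve(cov$S + diag(p)) else as.matrix(Omega0)

  rows <- list()
  sub_fit <- NULL
  converged <- FALSE
  t <- 0L
  while (t < max_dc_iter) {
    V <- subgradient_matrix(Omega_t, K)
    es <- find_eta(cov, V, alpha = alpha, pd_tolerance = pd_tolerance,
                   max_shrinks = max_eta_shrinks)
    sub_fit <- graphical_lasso(as_sample_covariance(cov$S - es$eta * V),
                               lambda = es$eta, eps = solver_eps,
                               max_iter = max_glasso_iter,
                               inner_tol = inner_tol,
                               inner_max_iter = inner_max_iter,
                               warm_start = if (t > 0L)
                                 list(Omega = Omega_t, Sigma = sub_fit$Sigma))
    Omega_new <- sub_fit$Omega
    delta <- sum((Omega_new - Omega_t)^2)
    t <- t + 1L
    rows[[t]] <- tibble::tibble(
      iteration = t,
      eta = es$eta,
      n_eig = es$n_eig,
      dc_objective = dc_objective(Omega_new, cov, K, es$eta),
      surrogate_objective = surrogate_objective(Omega_new, cov, K, es$eta,
                                                Omega_t, V = V),
      nnz = l0_norm(as.vector(Omega_new)),
      delta = delta
    )
    Omega_t <- Omega_new
    if (delta < eps) { converged <- TRUE; break }
  }

  trace <- dplyr::bind_rows(rows)
  res <- list(Omega = Omega_t, Sigma = sub_fit$Sigma,
              iterations = sub_fit$iterations,
              objective_trace = trace$dc_objective,
              converged = converged)
  new_ggm_fit(res, cov, method = "dc", penalty = NULL,
              extra = list(K = K, alpha = alpha,
                           dc_iterations = t,
                           n_eig = sum(trace$n_eig),
                           trace = trace))
}

#' Fit a cardinality-constrained Gaussian graphical model
#'
#' Data-frame-first interface to [dc_estimate()]: forms the sample
#' covariance, optionally applies diagonal shrinkage (required when
#' `n < p`, where the raw covariance is singular), and runs the DC
#' algorithm.
#'
#' @inheritParams ggm_glasso
#' @param K Cardinality budget on `vec(Omega)`; alternatively give `edges`.
#' @param edges Edge budget; translated to `K = p + 2 * edges`.
#' @param zeta Covariance shrinkage intensity; the default `NULL` uses the
#'   data-driven estimate of [estimate_shrinkage()] (raw data input only).
#'   Pass `0` to disable shrinkage.
#' @param ... Passed on to [dc_estimate()].
#' @return A `ggm_dc` fit.
#' @export
ggm_dc <- function(data, K = NULL, edges = NULL, zeta = NULL, ...) {
  cov <- resolve_shrunk_covariance(data, zeta)
  if (is.null(K)) {
    if (is.null(edges)) stop("supply either `K` or `edges`", call. = FALSE)
    K <- cov$p + 2L * edges
  }
  dc_estimate(cov, K = K, ...)
}
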
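#' Negative Gaussian log-likelihood of a precision matrix
#'
#' The scaled loss \eqn{-\log\det(\Omega) + \mathrm{tr}(\Omega S)}, whose
#' unpenalized minimizer over positive definite matrices is \eqn{S^{-1}}.
#'
#' @param Omega A symmetric positive definite p x p precision matrix.
#' @param S A `sample_covariance` object or symmetric matrix.
#' @return A single finite number.
#' @examples
#' neg_log_likelihood(diag(3), diag(3))  # 3
#' @export
neg_log_likelihood <- function(Omega, S) {
  Omega <- as.matrix(Omega)
  Smat <- as_sample_covariance(S)$S
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("Omega is not positive definite (smallest eigenvalue %.3e)", min(ev)),
         call. = FALSE)
  -sum(log(ev)) + sum(Omega * Smat)
}

#' Penalized negative log-likelihood
#'
#' Adds an element-wise L1 penalty over all p^2 entries (diagonal included) to
#' [neg_log_likelihood()]: `lambda * sum(abs(Omega))` for a scalar penalty, or
#' `sum(Lambda * abs(Omega))` when a weight matrix is supplied.
#'
#' @inheritParams neg_log_likelihood
#' @param lambda Nonnegative scalar penalty, or a p x p nonnegative symmetric
#'   weight matrix for an element-wise penalty.
#' @return A single number.
#' @export
penalized_objective <- function(Omega, S, lambda) {
  Omega <- as.matrix(Omega)
  L <- as_penalty_matrix(lambda, nrow(Omega))
  neg_log_likelihood(Omega, S) + sum(L * abs(Omega))
}

as_penalty_matrix <- function(lambda, p) {
  if (is.matrix(lambda)) {
    if (nrow(lambda) != p || ncol(lambda) != p)
      stop("penalty weight matrix must be p x p", call. = FALSE)
    if (any(lambda < 0)) stop("penalty weights must be nonnegative", call. = FALSE)
    if (max(abs(lambda - t(lambda))) > 1e-10)
      stop("penalty weight matrix must be symmetric", call. = FALSE)
    (lambda + t(lambda)) / 2
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
      stop("`lambda` must be a single nonnegative number or a weight matrix",
           call. = FALSE)
    matrix(lambda, p, p)
  }
}

#' Soft-thresholding operator
#'
#' `sign(x) * max(|x| - t, 0)`, the inner step of every lasso coordinate
#' update in the package.
#'
#' @param x Numeric vector.
#' @param t Nonnegative threshold.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' soft_threshold(c(0.7, -0.3), 0.5)
#' @export
soft_threshold <- function(x, t) {
  if (any(t < 0)) stop("threshold must be nonnegative", call. = FALSE)
  sign(x) * pmax(abs(x) - t, 0)
}

#' Graphical lasso solver
#'
#' Block coordinate-descent solver for the L1-penalized negative Gaussian
#' log-likelihood. The covariance iterate is initialized as `S + lambda * I`
#' (penalized diagonal); each sweep cycles over the columns in ascending
#' order, solving the column lasso subproblem by coordinate descent with
#' [soft_threshold()], and the sweep loop stops when the squared Frobenius
#' change of the precision iterate falls below `eps`. Zeros in the returned
#' precision matrix are exact. An element-wise penalty-weight matrix is
#' accepted in place of the scalar `lambda`, which is how the adaptive-lasso
#' and SCAD baselines reuse this solver.
#'
#' @param S A `sample_covariance` object or symmetric matrix.
#' @param lambda Scalar penalty (> 0 for singular `S`), or a p x p
#'   nonnegative symmetric weight matrix with positive diagonal.
#' @param eps Convergence threshold on the squared Frobenius norm of the
#'   change in the precision iterate between sweeps.
#' @param max_iter Maximum number of full column sweeps.
#' @param inner_tol,inner_max_iter Coordinate-descent tolerance (maximum
#'   absolute coefficient change per pass) and pass cap for each column lasso.
#' @param warm_start Optional list with `Omega` and `Sigma` from a previous
#'   solve on a nearby problem, used in place of the cold initialization.
#'   The DC algorithm warm-starts each convex subproblem at the incumbent
#'   iterate this way.
#' @return An object of class `ggm_fit`, a list with `Omega` (precision
#'   estimate, symmetric with exact zeros), `Sigma` (the solver's running
#'   covariance), `iterations`, `objective_trace` (penalized objective at
#'   initialization and after each sweep), `converged`, `penalty`, `p`, `n`.
#' @examples
#' S <- matrix(c(1, .8, .8, 1), 2)
#' fit <- graphical_lasso(S, lambda = 0.1)
#' fit$Sigma      # off-diagonal 0.7
#' @export
graphical_lasso <- function(S, lambda, eps = 1e-4, max_iter = 200L,
                            inner_tol = 1e-6, inner_max_iter = 1000L,
                            warm_start = NULL) {
  cov <- as_sample_covariance(S)
  if (eps <= 0 || inner_tol <= 0) stop("tolerances must be positive", call. = FALSE)
  if (max_iter < 1L || inner_max_iter < 1L) stop("iteration caps must be >= 1", call. = FALSE)
  L <- as_penalty_matrix(lambda, cov$p)
  res <- .glasso_cpp(cov$S, L, eps, as.integer(max_iter),
                     inner_tol, as.integer(inner_max_iter),
                     warm_start$Omega, warm_start$Sigma)
  new_ggm_fit(res, cov, method = "glasso",
              penalty = if (is.matrix(lambda)) L else lambda)
}

new_ggm_fit <- function(res, cov, method, penalty, extra = list()) {
  out <- c(list(
    Omega = res$Omega,
    Sigma = res$Sigma,
    iterations = res$iterations,
    objective_trace = res$objective_trace,
    converged = res$converged,
    method = method,
    penalty = penalty,
    p = cov$p,
    n = cov$n,
    S = cov$S
  ), extra)
  class(out) <- c(paste0("ggm_", method), "ggm_fit")
  out
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf("<ggm_fit: %s> p = %d, edges = %d, sweeps = %d, converged = %s\n",
              x$method, x$p, count_edges(x$Omega), x$iterations, x$converged))
  invisible(x)
}

#' Fit a Gaussian graphical model by the graphical lasso
#'
#' Data-frame-first interface: forms the sample covariance of `data` (or uses
#' a supplied `sample_covariance`) and calls [graphical_lasso()].
#'
#' @param data Data frame or matrix of observations (rows) by variables
#'   (columns), or a `sample_covariance`.
#' @inheritParams graphical_lasso
#' @param zeta Optional covariance shrinkage intensity applied before
#'   fitting (see [shrink_covariance()]); `0` disables shrinkage.
#' @param ... Passed on to [graphical_lasso()].
#' @return A `ggm_fit` object.
#' @export
ggm_glasso <- function(data, lambda, zeta = 0, ...) {
  cov <- resolve_shrunk_covariance(data, zeta)
  graphical_lasso(cov, lambda, ...)
}
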
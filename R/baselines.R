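#' SCAD penalty function
#'
#' Smoothly clipped absolute deviation penalty: `lambda * |x|` for
#' `|x| <= lambda`, the quadratic blend
#' `(a*lambda*|x| - (x^2 + lambda^2)/2) / (a - 1)` for
#' `lambda < |x| <= a*lambda`, and the constant `(a + 1) * lambda^2 / 2`
#' beyond, so large entries are eventually unpenalized. Continuous at both
#' breakpoints.
#'
#' @param x Numeric vector.
#' @param lambda Positive penalty level.
#' @param a Shape parameter, must exceed 2 (default 3.7, the conventional
#'   choice).
#' @return Numeric vector of penalty values.
#' @examples
#' scad_penalty(c(0, 0.5, 5), lambda = 0.5)
#' @export
scad_penalty <- function(x, lambda, a = 3.7) {
  check_scad_params(lambda, a)
  ax <- abs(x)
  ifelse(ax <= lambda, lambda * ax,
         ifelse(ax <= a * lambda,
                (a * lambda * ax - (ax^2 + lambda^2) / 2) / (a - 1),
                (a + 1) * lambda^2 / 2))
}

#' SCAD penalty derivative
#'
#' Right derivative of [scad_penalty()] in `|x|`; used as the local-linear
#' weight in the iterated reweighting scheme of [ggm_scad()].
#'
#' @inheritParams scad_penalty
#' @return Numeric vector of nonnegative weights.
#' @export
scad_derivative <- function(x, lambda, a = 3.7) {
  check_scad_params(lambda, a)
  ax <- abs(x)
  ifelse(ax <= lambda, lambda,
         ifelse(ax <= a * lambda, (a * lambda - ax) / (a - 1), 0))
}

check_scad_params <- function(lambda, a) {
  if (lambda <= 0) stop("`lambda` must be positive", call. = FALSE)
  if (a <= 2) stop("SCAD parameter `a` must exceed 2", call. = FALSE)
}

#' Adaptive-lasso penalty weights
#'
#' Element-wise weights `1 / |pilot|^gamma` from a consistent pilot estimate
#' of the precision matrix. Zero pilot entries would give infinite weights;
#' they are capped at `cap`, which effectively forbids those edges.
#'
#' @param pilot Symmetric pilot precision matrix.
#' @param gamma Positive weight exponent.
#' @param cap Upper bound substituted for infinite weights.
#' @return A p x p nonnegative symmetric weight matrix.
#' @examples
#' adaptive_weights(matrix(c(1, .25, .25, 1), 2), gamma = 0.5)
#' @export
adaptive_weights <- function(pilot, gamma = 0.5, cap = 1e12) {
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  W <- 1 / abs(as.matrix(pilot))^gamma
  W[!is.finite(W)] <- cap
  pmin(W, cap)
}

# Pilot precision: inverse covariance, with a ridge fallback when S is
# numerically singular (n < p). The ridge level is proportional to the mean
# diagonal so it is scale-equivariant.
pilot_precision <- function(cov, ridge = 1e-2) {
  inv <- tryCatch(solve(cov$S), error = function(e) NULL)
  if (is.null(inv) || min(eigen(cov$S, symmetric = TRUE,
                                only.values = TRUE)$values) <= 1e-10) {
    inv <- solve(cov$S + ridge * mean(diag(cov$S)) * diag(cov$p))
  }
  inv
}

#' Adaptive-lasso precision estimation
#'
#' One weighted graphical lasso solve with element-wise penalty
#' `lambda * adaptive_weights(pilot, gamma)`. The default pilot is the
#' inverse (optionally shrunk) sample covariance; a ridge-regularized inverse
#' is substituted when that matrix is numerically singular.
#'
#' @inheritParams ggm_glasso
#' @param gamma Weight exponent (default 0.5).
#' @param pilot Optional pilot precision matrix; default `solve(S)` with a
#'   ridge fallback.
#' @param weight_cap Cap for infinite weights at zero pilot entries.
#' @return A `ggm_fit` object (method `"adaptive"`).
#' @export
ggm_adaptive <- function(data, lambda, gamma = 0.5, pilot = NULL,
                         weight_cap = 1e12, zeta = 0, ...) {
  cov <- resolve_shrunk_covariance(data, zeta)
  if (is.null(pilot)) pilot <- pilot_precision(cov)
  W <- adaptive_weights(pilot, gamma = gamma, cap = weight_cap)
  fit <- graphical_lasso(cov, lambda * W, ...)
  fit$method <- "adaptive"
  class(fit) <- c("ggm_adaptive", "ggm_fit")
  fit
}

#' SCAD-penalized precision estimation
#'
#' Iterated local linear approximation: the first round is a plain graphical
#' lasso at `lambda` (the SCAD derivative at 0 is `lambda`); each subsequent
#' round re-solves the weighted graphical lasso with element-wise weights
#' `scad_derivative(abs(Omega_hat), lambda, a)` evaluated at the current
#' estimate, until the selected support stabilizes or `max_rounds` rounds.
#'
#' @inheritParams ggm_glasso
#' @param a SCAD shape parameter (> 2, default 3.7).
#' @param max_rounds Cap on reweighting rounds.
#' @return A `ggm_fit` object (method `"scad"`) with an extra field
#'   `rounds`.
#' @export
ggm_scad <- function(data, lambda, a = 3.7, max_rounds = 5L, zeta = 0, ...) {
  check_scad_params(lambda, a)
  cov <- resolve_shrunk_covariance(data, zeta)
  fit <- graphical_lasso(cov, lambda, ...)
  support <- fit$Omega != 0
  rounds <- 1L
  while (rounds < max_rounds) {
    W <- scad_derivative(abs(fit$Omega), lambda, a)
    # keep the covariance initialization invertible: SCAD leaves large
    # diagonal entries unpenalized, which is fine for positive definite S
    fit_new <- tryCatch(graphical_lasso(cov, W, ...), error = function(e) NULL)
    if (is.null(fit_new)) break
    rounds <- rounds + 1L
    fit <- fit_new
    support_new <- fit$Omega != 0
    if (identical(support, support_new)) break
    support <- support_new
  }
  fit$method <- "scad"
  class(fit) <- c("ggm_scad", "ggm_fit")
  fit$rounds <- rounds
  fit
}
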
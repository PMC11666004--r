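#' Sample covariance of a data set
#'
#' Centers each variable by its sample mean and forms
#' \eqn{S = (1/n) \sum_i (x_i - m)(x_i - m)^\top} (divisor `n`, the maximum
#' likelihood convention). This is the sole data summary consumed by all
#' estimators in the package.
#'
#' @param data A data frame or numeric matrix with observations in rows and
#'   variables in columns.
#' @return An object of class `sample_covariance`: a list with elements `S`
#'   (p x p matrix), `p`, `n` and `mean` (the sample mean used for centering).
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' S <- sample_covariance(x)
#' S$p
#' @export
sample_covariance <- function(data) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("`data` must be numeric", call. = FALSE)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  m <- colMeans(x)
  xc <- sweep(x, 2L, m)
  S <- crossprod(xc) / n
  new_sample_covariance(S, n = n, mean = m)
}

#' Wrap an existing covariance matrix
#'
#' @param S A symmetric p x p covariance (or second-moment) matrix.
#' @param n Optional sample size, kept for cross-validation bookkeeping.
#' @return A `sample_covariance` object.
#' @export
as_sample_covariance <- function(S, n = NULL) {
  if (inherits(S, "sample_covariance")) return(S)
  S <- as.matrix(S)
  new_sample_covariance(S, n = n, mean = NULL)
}

new_sample_covariance <- function(S, n = NULL, mean = NULL) {
  p <- nrow(S)
  if (p < 2L || ncol(S) != p) stop("covariance must be square with p >= 2", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-10) stop("covariance matrix is not symmetric", call. = FALSE)
  if (any(diag(S) < 0)) stop("covariance diagonal must be nonnegative", call. = FALSE)
  S <- (S + t(S)) / 2
  dimnames(S) <- NULL
  structure(list(S = S, p = p, n = n, mean = mean), class = "sample_covariance")
}

#' @export
print.sample_covariance <- function(x, ...) {
  cat(sprintf("<sample_covariance> p = %d, n = %s\n", x$p,
              if (is.null(x$n)) "?" else x$n))
  invisible(x)
}

# Resolve data-frame / matrix / sample_covariance input to a
# sample_covariance. Square symmetric matrices are ambiguous; `data` is always
# treated as observations unless wrapped by as_sample_covariance().
resolve_covariance <- function(data) {
  if (inherits(data, "sample_covariance")) data else sample_covariance(data)
}

#' Estimate the diagonal-shrinkage intensity from data
#'
#' Analytic optimal intensity for shrinking the sample correlation matrix
#' towards the identity (equivalently, the covariance towards its diagonal),
#' in the Ledoit-Wolf / Schaefer-Strimmer style: the ratio of the summed
#' estimated variances of the off-diagonal sample correlations to their
#' summed squares, truncated to `[0, 1]`. Small samples with weak
#' correlation structure yield intensities near 1 (heavy shrinkage); large,
#' strongly correlated samples yield smaller values. This estimate is the
#' package-wide default shrinkage for the DC solver, which requires a
#' positive definite covariance.
#'
#' @param data Data frame or matrix of observations by variables.
#' @return A single value in `[0, 1]`.
#' @examples
#' truth <- make_chain_graph_precision(20, seed = 1)
#' estimate_shrinkage(sample_ggm_data(truth, 40, seed = 2))
#' @export
estimate_shrinkage <- function(data) {
  x <- as.matrix(data)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0   # constant columns carry no signal
  w_bar <- crossprod(xs) / n
  var_r <- (n / (n - 1)^3) * (crossprod(xs^2) - n * w_bar^2)
  r <- (n / (n - 1)) * w_bar
  num <- sum(var_r[upper.tri(var_r)])
  den <- sum(r[upper.tri(r)]^2)
  if (den == 0) return(1)
  max(0, min(1, num / den))
}

# zeta = NULL -> data-driven intensity; needs raw data, not a covariance
resolve_shrunk_covariance <- function(data, zeta) {
  if (inherits(data, "sample_covariance")) {
    if (is.null(zeta)) return(data)
    return(shrink_covariance(data, zeta))
  }
  if (is.null(zeta)) zeta <- estimate_shrinkage(data)
  shrink_covariance(sample_covariance(data), zeta)
}

#' Shrink a covariance matrix towards its diagonal
#'
#' Computes the convex combination \eqn{\zeta D_S + (1 - \zeta) S} where
#' \eqn{D_S} is the diagonal part of `S`. The diagonal is unchanged and the
#' off-diagonal entries are scaled by `1 - zeta`; for any `zeta > 0` and a
#' strictly positive diagonal the result is positive definite whenever `S` is
#' positive semidefinite, which the DC solver requires when `n < p`.
#'
#' @param S A `sample_covariance` object or symmetric matrix.
#' @param zeta Shrinkage intensity in `[0, 1]`.
#' @return A `sample_covariance` object.
#' @examples
#' S <- as_sample_covariance(matrix(c(1, .8, .8, 1), 2))
#' shrink_covariance(S, 0.5)$S
#' @export
shrink_covariance <- function(S, zeta) {
  if (!is.numeric(zeta) || length(zeta) != 1L || zeta < 0 || zeta > 1)
    stop("`zeta` must be a single value in [0, 1]", call. = FALSE)
  cov <- as_sample_covariance(S)
  M <- cov$S
  M[row(M) != col(M)] <- (1 - zeta) * M[row(M) != col(M)]
  new_sample_covariance(M, n = cov$n, mean = cov$mean)
}
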
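#' L0 pseudo-norm
#'
#' Number of exactly nonzero entries of a vector. Support in this package is
#' always read by exact-zero comparison: the solvers produce exact zeros via
#' soft-thresholding, so no magnitude cutoff is applied.
#'
#' @param w Numeric vector.
#' @return Integer count.
#' @examples
#' l0_norm(c(1, 0, 2))  # 2
#' @export
l0_norm <- function(w) {
  sum(w != 0)
}

#' Largest-K norm
#'
#' Sum of the `K` largest absolute entries of `w`. This convex function
#' rewrites the cardinality constraint: `||w||_0 <= K` holds exactly when
#' `sum(abs(w)) - largest_k_norm(w, K) == 0`.
#'
#' @param w Numeric vector of length m.
#' @param K Integer in `[1, m]`.
#' @return A single number.
#' @examples
#' largest_k_norm(c(3, -1, 2), 2)  # 5
#' @export
largest_k_norm <- function(w, K) {
  check_k_range(K, length(w))
  a <- sort(abs(w), decreasing = TRUE)
  sum(a[seq_len(K)])
}

check_k_range <- function(K, m) {
  if (length(K) != 1L || K != round(K) || K < 1L || K > m)
    stop(sprintf("K must be an integer in [1, %d]", m), call. = FALSE)
}

#' Subgradient of the largest-K norm
#'
#' Returns `sign(w[i])` on the K positions with the largest absolute values
#' (ties broken by lowest index, so runs are deterministic) and 0 elsewhere.
#' The sign convention maps 0 to 0. The returned vector `s` satisfies
#' `sum(s * w) == largest_k_norm(w, K)`.
#'
#' @inheritParams largest_k_norm
#' @return Integer vector in `{-1, 0, 1}` of the same length as `w`.
#' @examples
#' topk_subgradient(c(3, -1, 2), 2)  # 1 0 1
#' @export
topk_subgradient <- function(w, K) {
  check_k_range(K, length(w))
  ord <- order(-abs(w), seq_along(w))
  s <- integer(length(w))
  sel <- ord[seq_len(K)]
  s[sel] <- sign(w[sel])
  s
}

#' Symmetry-preserving subgradient matrix for the DC algorithm
#'
#' Matrix form of the largest-K subgradient used in the DC iteration, chosen
#' so that the modified covariance `S - eta * V` stays a valid solver input:
#' all p diagonal positions are selected first (the diagonal of a positive
#' definite precision matrix is always nonzero, so the diagonal of `V` is 1),
#' and the remaining `K - p` slots are filled by the largest off-diagonal
#' absolute values in symmetric pairs. If `K - p` is odd the last unpaired
#' slot is left empty, so `V` never has more than `K` nonzero entries. Ties
#' are broken by lowest (row, column) index.
#'
#' @param Omega Symmetric p x p matrix with strictly positive diagonal.
#' @param K Cardinality budget on `vec(Omega)`, an integer in `[p, p^2]`.
#' @return A symmetric p x p matrix with entries in `{-1, 0, 1}` and unit
#'   diagonal.
#' @export
subgradient_matrix <- function(Omega, K) {
  Omega <- as.matrix(Omega)
  p <- nrow(Omega)
  if (ncol(Omega) != p || max(abs(Omega - t(Omega))) > 1e-8)
    stop("Omega must be symmetric", call. = FALSE)
  if (any(diag(Omega) <= 0))
    stop("Omega must have a strictly positive diagonal", call. = FALSE)
  if (length(K) != 1L || K != round(K) || K < p || K > p * p)
    stop(sprintf("K must be an integer in [p, p^2] = [%d, %d]", p, p * p),
         call. = FALSE)

  V <- diag(p)
  n_pairs <- (K - p) %/% 2
  if (n_pairs > 0) {
    ut <- which(upper.tri(Omega), arr.ind = TRUE)     # col-major: j then i
    vals <- Omega[ut]
    ord <- order(-abs(vals), ut[, 1L], ut[, 2L])
    sel <- ord[seq_len(min(n_pairs, nrow(ut)))]
    for (s in sel) {
      i <- ut[s, 1L]; j <- ut[s, 2L]
      V[i, j] <- V[j, i] <- sign(Omega[i, j])
    }
  }
  V
}
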
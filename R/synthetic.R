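#' Random-graph ground-truth precision matrix
#'
#' Draws `A1` with independent standard normal entries, symmetrizes it as
#' `A2 = (A1 + t(A1)) / 2`, keeps exactly `n_true_edges` uniformly chosen
#' off-diagonal pairs (zeroing the rest symmetrically; the diagonal is kept
#' as drawn), and adds `eta_rnd * I` with `eta_rnd` chosen so the smallest
#' eigenvalue equals 1. Positive definiteness is therefore guaranteed by
#' construction.
#'
#' @param p Number of variables (>= 2).
#' @param n_true_edges Number of true edges, between 0 and `p*(p-1)/2`
#'   (default 30, the benchmark setting used throughout the package).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `ggm_truth`: a list with `Omega` (true
#'   precision matrix), `Sigma` (its inverse), `edges` (tibble of true edges
#'   `i < j` with their precision values), `graph`, `p`, `n_true_edges`.
#' @examples
#' truth <- make_random_graph_precision(10, n_true_edges = 10, seed = 1)
#' min(eigen(truth$Omega)$values)  # 1
#' @export
make_random_graph_precision <- function(p, n_true_edges = 30L, seed = NULL) {
  if (p < 2L) stop("p must be >= 2", call. = FALSE)
  max_pairs <- p * (p - 1) / 2
  if (n_true_edges < 0 || n_true_edges > max_pairs)
    stop(sprintf("n_true_edges must be in [0, %d]", max_pairs), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  A1 <- matrix(rnorm(p * p), p, p)
  A2 <- (A1 + t(A1)) / 2
  keep <- sample.int(max_pairs, n_true_edges)
  Omega <- diag(diag(A2))
  ut <- which(upper.tri(A2), arr.ind = TRUE)
  for (s in keep) {
    i <- ut[s, 1L]; j <- ut[s, 2L]
    Omega[i, j] <- Omega[j, i] <- A2[i, j]
  }
  lmin <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
  Omega <- Omega + (1 - lmin) * diag(p)
  new_ggm_truth(Omega, graph = "random")
}

#' Chain-graph ground-truth precision matrix
#'
#' Builds the banded matrix with 1 on the diagonal, 0.5 on the first
#' off-diagonal and 0.25 on the second, then randomly zeroes band pairs
#' (symmetrically) until exactly `n_true_edges` remain. Since zeroing can in
#' principle destroy positive definiteness, the zero pattern is redrawn up to
#' `max_retries` times and an error is raised if no positive definite
#' pattern is found.
#'
#' @inheritParams make_random_graph_precision
#' @param n_true_edges Number of retained band edges, at most `2p - 3`
#'   (default: the full band).
#' @param max_retries Redraws of the zero pattern allowed before giving up.
#' @return A `ggm_truth` object.
#' @examples
#' make_chain_graph_precision(5)$Omega
#' @export
make_chain_graph_precision <- function(p, n_true_edges = 2L * p - 3L,
                                       seed = NULL, max_retries = 50L) {
  if (p < 3L) stop("p must be >= 3 for a chain graph", call. = FALSE)
  n_band <- 2L * p - 3L
  if (n_true_edges < 0 || n_true_edges > n_band)
    stop(sprintf("n_true_edges must be in [0, %d]", n_band), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  D <- abs(row(diag(p)) - col(diag(p)))
  base <- ifelse(D == 0, 1, ifelse(D == 1, 0.5, ifelse(D == 2, 0.25, 0)))
  band <- which(upper.tri(base) & base > 0, arr.ind = TRUE)

  for (try in seq_len(max_retries)) {
    keep <- sample.int(nrow(band), n_true_edges)
    Omega <- diag(p)
    for (s in keep) {
      i <- band[s, 1L]; j <- band[s, 2L]
      Omega[i, j] <- Omega[j, i] <- base[i, j]
    }
    lmin <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin > 1e-10) return(new_ggm_truth(Omega, graph = "chain"))
  }
  stop("no positive definite zero pattern found after ", max_retries,
       " retries", call. = FALSE)
}

new_ggm_truth <- function(Omega, graph) {
  p <- nrow(Omega)
  ut <- which(upper.tri(Omega) & Omega != 0, arr.ind = TRUE)
  edges <- tibble::tibble(i = ut[, 1L], j = ut[, 2L],
                          value = Omega[ut])
  structure(list(Omega = Omega, Sigma = solve(Omega), edges = edges,
                 graph = graph, p = p, n_true_edges = nrow(edges)),
            class = "ggm_truth")
}

#' @export
print.ggm_truth <- function(x, ...) {
  cat(sprintf("<ggm_truth: %s graph> p = %d, true edges = %d\n",
              x$graph, x$p, x$n_true_edges))
  invisible(x)
}

#' Sample observations from a ground-truth model
#'
#' Draws `n` independent observations from the zero-mean multivariate normal
#' with covariance `truth$Sigma` (via a Cholesky factor).
#'
#' @param truth A `ggm_truth` object (or any list with a `Sigma` matrix).
#' @param n Number of observations (>= 2).
#' @param seed Optional integer seed.
#' @return A tibble with `n` rows and `p` columns `V1 ... Vp`.
#' @export
sample_ggm_data <- function(truth, n, seed = NULL) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Sigma <- truth$Sigma
  p <- nrow(Sigma)
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z %*% chol(Sigma)
  colnames(X) <- paste0("V", seq_len(p))
  tibble::as_tibble(X)
}

#' Simulate one benchmark instance
#'
#' Convenience wrapper for the full data-generation pipeline: draw a
#' ground-truth precision matrix, sample `n` observations, form the sample
#' covariance and shrink it towards its diagonal with intensity `zeta`.
#'
#' @param graph `"random"` or `"chain"`.
#' @param p,n Number of variables and observations.
#' @param n_true_edges Number of true edges (default 30).
#' @param zeta Shrinkage intensity for the sample covariance; the default
#'   `NULL` estimates it from the sampled data via [estimate_shrinkage()].
#'   Some shrinkage is required for the DC solver whenever `n < p`.
#' @param seed Optional integer seed controlling both the truth and the
#'   sampled data.
#' @return A list with `truth` (a `ggm_truth`), `data` (tibble of
#'   observations), `S` (shrunk `sample_covariance`) and `zeta` (the
#'   shrinkage intensity used).
#' @export
simulate_ggm <- function(graph = c("random", "chain"), p, n,
                         n_true_edges = 30L, zeta = NULL, seed = NULL) {
  graph <- match.arg(graph)
  truth <- switch(graph,
                  random = make_random_graph_precision(p, n_true_edges, seed = seed),
                  chain = make_chain_graph_precision(p, n_true_edges, seed = seed))
  x <- sample_ggm_data(truth, n)
  if (is.null(zeta)) zeta <- estimate_shrinkage(x)
  S <- shrink_covariance(sample_covariance(x), zeta)
  list(truth = truth, data = x, S = S, zeta = zeta)
}
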
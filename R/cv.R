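#' Cardinality grid for cross-validation
#'
#' 100 equally spaced values between `p + 2` and `p^2`, rounded to the
#' nearest integer and deduplicated with order preserved.
#'
#' @param p Number of variables (>= 2).
#' @param length_out Grid size before deduplication (default 100).
#' @return Integer vector of cardinality budgets.
#' @examples
#' range(k_grid(50))  # 52, 2500
#' @export
k_grid <- function(p, length_out = 100L) {
  if (p < 2L) stop("p must be >= 2", call. = FALSE)
  unique(round(seq(p + 2, p * p, length.out = length_out)))
}

#' Regularization grid for the L1/adaptive/SCAD baselines
#'
#' 100 equally spaced values in `[0, lambda_max]` with
#' `lambda_max = max |off-diagonal S|`, the smallest penalty at which the
#' graphical lasso support is empty.
#'
#' @param S A `sample_covariance` or symmetric matrix.
#' @param length_out Grid size (default 100).
#' @return Numeric vector; a warning is issued for the degenerate all-zero
#'   grid that arises when `S` is diagonal.
#' @export
lambda_grid <- function(S, length_out = 100L) {
  Smat <- as_sample_covariance(S)$S
  lambda_max <- max(abs(Smat[upper.tri(Smat)]))
  if (lambda_max == 0)
    warning("S has no nonzero off-diagonal entries; the grid is degenerate at 0")
  seq(0, lambda_max, length.out = length_out)
}

fit_at <- function(S, method, value, ...) {
  switch(method,
         dc = dc_estimate(S, K = value, ...),
         glasso = graphical_lasso(S, lambda = value, ...),
         adaptive = ggm_adaptive(S, lambda = value, ...),
         scad = ggm_scad(S, lambda = value, ...))
}

#' Cross-validated selection of the edge budget or penalty level
#'
#' 5-fold (by default) cross-validation of the Gaussian validation
#' log-likelihood. For each fold the model is fitted on the training
#' portion's shrinkage-adjusted sample covariance at every grid value and
#' scored on the held-out fold by `log det(Omega) - tr(Omega S_val)`, where
#' `S_val` is the validation fold's own centered covariance (no shrinkage on
#' the validation side). The grid value maximizing the mean held-out
#' log-likelihood is selected -- ties go to the sparser model (smallest `K`,
#' largest `lambda`) -- and the model is refitted on the full data.
#'
#' @param data Data frame or matrix of observations by variables.
#' @param method One of `"dc"`, `"glasso"`, `"adaptive"`, `"scad"`.
#' @param grid Parameter grid: cardinality budgets for `"dc"`, penalty
#'   levels otherwise. Defaults to [k_grid()] / [lambda_grid()]. For the
#'   baselines a zero penalty is only usable when the training covariance is
#'   nonsingular; such grid points are dropped with a message if they fail.
#' @param folds Number of folds (default 5).
#' @param seed Optional seed controlling the fold assignment.
#' @param zeta Shrinkage intensity applied to each training covariance and
#'   to the final refit; `NULL` (default) estimates it from the training
#'   portion via [estimate_shrinkage()].
#' @param ... Passed to the underlying fitting function.
#' @return An object of class `ggm_cv`: list with `curve` (tibble of grid
#'   value, mean held-out log-likelihood, mean selected edge count),
#'   `selected` (the chosen grid value), `fit` (refit on the full data),
#'   `method`, `fold_id`.
#' @export
ggm_cv <- function(data, method = c("dc", "glasso", "adaptive", "scad"),
                   grid = NULL, folds = 5L, seed = NULL, zeta = NULL, ...) {
  method <- match.arg(method)
  x <- as.matrix(data)
  n <- nrow(x)
  if (n < folds) stop("need at least `folds` observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))

  if (is.null(grid)) {
    grid <- if (method == "dc") k_grid(ncol(x)) else
      lambda_grid(resolve_shrunk_covariance(x, zeta))
  }
  grid <- unique(grid)

  score <- matrix(NA_real_, length(grid), folds)
  edges <- matrix(NA_real_, length(grid), folds)
  for (f in seq_len(folds)) {
    S_train <- resolve_shrunk_covariance(x[fold_id != f, , drop = FALSE], zeta)
    S_val <- sample_covariance(x[fold_id == f, , drop = FALSE])$S
    for (g in seq_along(grid)) {
      fit <- tryCatch(fit_at(S_train, method, grid[g], ...),
                      error = function(e) NULL)
      if (is.null(fit)) next
      ev <- eigen(fit$Omega, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) next
      score[g, f] <- sum(log(ev)) - sum(fit$Omega * S_val)
      edges[g, f] <- count_edges(fit$Omega)
    }
  }

  curve <- tibble::tibble(
    value = grid,
    mean_loglik = rowMeans(score),
    mean_edges = rowMeans(edges)
  )
  ok <- which(is.finite(curve$mean_loglik))
  if (length(ok) == 0) stop("no grid value produced a valid fit", call. = FALSE)
  best <- max(curve$mean_loglik[ok])
  cand <- ok[curve$mean_loglik[ok] == best]
  selected <- if (method == "dc") grid[min(cand)] else grid[max(cand)]

  S_full <- resolve_shrunk_covariance(x, zeta)
  final <- fit_at(S_full, method, selected, ...)

  structure(list(curve = curve, selected = selected, fit = final,
                 method = method, fold_id = fold_id),
            class = "ggm_cv")
}

#' @export
print.ggm_cv <- function(x, ...) {
  cat(sprintf("<ggm_cv: %s> selected %s = %s, edges = %d\n",
              x$method, if (x$method == "dc") "K" else "lambda",
              format(x$selected), count_edges(x$fit$Omega)))
  invisible(x)
}
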
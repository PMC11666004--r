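#' Tidy an estimated Gaussian graphical model
#'
#' One row per selected edge (upper triangle, 1-based indices) with the
#' estimated precision value and the implied partial correlation
#' `-omega_ij / sqrt(omega_ii * omega_jj)`.
#'
#' @param x A `ggm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `node_i`, `node_j`, `precision`,
#'   `partial_cor`.
#' @export
tidy.ggm_fit <- function(x, ...) {
  O <- x$Omega
  ut <- which(upper.tri(O) & O != 0, arr.ind = TRUE)
  tibble::tibble(
    node_i = as.integer(ut[, 1L]),
    node_j = as.integer(ut[, 2L]),
    precision = O[ut],
    partial_cor = -O[ut] / sqrt(diag(O)[ut[, 1L]] * diag(O)[ut[, 2L]])
  ) |> dplyr::arrange(.data$node_i, .data$node_j)
}

#' Glance at an estimated Gaussian graphical model
#'
#' @param x A `ggm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `p`, `n_edges`, `nnz` (nonzeros of
#'   `vec(Omega)`), `iterations`, `converged`, `neg_loglik` and, for DC
#'   fits, `K`, `dc_iterations`, `n_eig`.
#' @export
glance.ggm_fit <- function(x, ...) {
  base <- tibble::tibble(
    method = x$method, p = x$p, n_edges = count_edges(x$Omega),
    nnz = l0_norm(as.vector(x$Omega)), iterations = x$iterations,
    converged = x$converged,
    neg_loglik = neg_log_likelihood(x$Omega, x$S))
  if (x$method == "dc")
    base <- dplyr::bind_cols(base, tibble::tibble(
      K = x$K, dc_iterations = x$dc_iterations, n_eig = x$n_eig))
  base
}

#' @rdname tidy.ggm_fit
#' @export
tidy.ggm_truth <- function(x, ...) {
  dplyr::rename(x$edges, node_i = "i", node_j = "j", precision = "value")
}

#' Tidy a cross-validation result
#'
#' @param x A `ggm_cv`.
#' @param ... Unused.
#' @return The CV curve as a tibble: grid `value`, `mean_loglik`,
#'   `mean_edges`.
#' @export
tidy.ggm_cv <- function(x, ...) x$curve

#' @rdname tidy.ggm_cv
#' @export
glance.ggm_cv <- function(x, ...) {
  tibble::tibble(method = x$method, selected = x$selected,
                 selected_edges = count_edges(x$fit$Omega),
                 folds = max(x$fold_id))
}

#' Plot a cross-validation curve
#'
#' Mean held-out log-likelihood against the mean number of selected edges,
#' with the selected model marked.
#'
#' @param object A `ggm_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ggm_cv <- function(object, ...) {
  sel <- object$curve[object$curve$value == object$selected, ]
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$mean_edges, y = .data$mean_loglik)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = sel, color = "red", size = 2) +
    ggplot2::labs(x = "mean selected edges",
                  y = "mean held-out log-likelihood",
                  title = sprintf("%s cross-validation", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot the DC iteration trace
#'
#' DC objective value and penalty parameter per outer iteration.
#'
#' @param object A `ggm_dc` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ggm_dc <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              c("dc_objective", "eta", "nnz"),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "outer DC iteration", y = NULL) +
    ggplot2::theme_minimal()
}
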
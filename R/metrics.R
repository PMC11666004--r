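#' Count selected edges of a precision matrix
#'
#' Number of unordered pairs `j < k` with an exactly nonzero entry.
#'
#' @param Omega A symmetric precision matrix or a `ggm_fit`.
#' @return Integer edge count.
#' @export
count_edges <- function(Omega) {
  M <- if (inherits(Omega, "ggm_fit")) Omega$Omega else as.matrix(Omega)
  sum(M[upper.tri(M)] != 0)
}

#' Edge-recovery confusion counts and F1 score
#'
#' Compares the off-diagonal supports (exact-zero reading, pairs `j < k`) of
#' an estimated and a true precision matrix. Precision, recall and F1 follow
#' the usual definitions; undefined 0/0 ratios are reported as 0.
#'
#' @param estimate A `ggm_fit` or symmetric precision matrix.
#' @param truth A `ggm_truth` or symmetric precision matrix of the same
#'   dimension.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @examples
#' est <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3)
#' tru <- diag(3); tru[2, 3] <- tru[3, 2] <- 0.5
#' edge_confusion(est, tru)
#' @export
edge_confusion <- function(estimate, truth) {
  E <- if (inherits(estimate, "ggm_fit")) estimate$Omega else as.matrix(estimate)
  Tm <- if (inherits(truth, "ggm_truth")) truth$Omega else as.matrix(truth)
  if (!all(dim(E) == dim(Tm)))
    stop("estimate and truth must have the same dimension", call. = FALSE)
  eh <- E[upper.tri(E)] != 0
  et <- Tm[upper.tri(Tm)] != 0
  tp <- sum(eh & et)
  fp <- sum(eh & !et)
  fn <- sum(!eh & et)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = prec, recall = rec, f1 = f1)
}
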
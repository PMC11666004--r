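#' Read a numeric data or covariance matrix from delimited text
#'
#' Reads CSV (default) or TSV into a plain numeric matrix. Whether the file
#' holds raw observations or a covariance matrix is up to the caller; wrap a
#' covariance with [as_sample_covariance()].
#'
#' @param path File path.
#' @param sep Field separator; `","` or `"\t"`.
#' @param header Does the first line hold column names? Default `FALSE`.
#' @return A numeric matrix.
#' @export
read_matrix <- function(path, sep = ",", header = FALSE) {
  as.matrix(utils::read.table(path, sep = sep, header = header))
}

#' Write an estimated precision matrix and its edge list
#'
#' `write_precision()` writes the p x p precision estimate as headerless
#' CSV. `write_edges()` writes the selected support as a 3-column TSV
#' (`node_i`, `node_j`, `precision`; 1-based indices, upper triangle only).
#'
#' @param fit A `ggm_fit` (or precision matrix).
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_precision <- function(fit, path) {
  M <- if (inherits(fit, "ggm_fit")) fit$Omega else as.matrix(fit)
  utils::write.table(M, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(fit)
}

#' @rdname write_precision
#' @export
write_edges <- function(fit, path) {
  M <- if (inherits(fit, "ggm_fit")) fit$Omega else as.matrix(fit)
  ut <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  df <- data.frame(node_i = ut[, 1L], node_j = ut[, 2L], precision = M[ut])
  df <- df[order(df$node_i, df$node_j), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(fit)
}
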
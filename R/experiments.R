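#' Define a replicate benchmark experiment
#'
#' Describes a grid of synthetic-benchmark cells (graph kind x dimension x
#' sample size), the methods to run in each cell, and the replication and
#' seeding policy. The default per-cell parameters follow the fixed-budget
#' protocol: the DC cardinality budget is `K = p * (p - 1) / 4` (half of all
#' ordered off-diagonal slots) and the baseline penalty is the median
#' absolute off-diagonal entry of the shrunk sample covariance.
#'
#' @param graph Character vector from `"random"`, `"chain"`.
#' @param p Integer vector of variable counts.
#' @param n Sample sizes: either an explicit integer vector crossed with
#'   `p`, or one of the rule strings `"p/2"`, `"p"`, `"2p"`.
#' @param n_true_edges True edge count per instance (default 30).
#' @param replicates Replicates per cell (default 30).
#' @param methods Methods to run; subset of `"dc"`, `"glasso"`,
#'   `"adaptive"`, `"scad"`.
#' @param K Optional fixed DC budget (defaults to `p * (p - 1) / 4`).
#' @param lambda Optional fixed baseline penalty (defaults to the median
#'   absolute off-diagonal of S).
#' @param zeta Covariance shrinkage intensity; `NULL` (default) estimates
#'   it per replicate from the sampled data.
#' @param seed Base seed; per-replicate seeds are derived deterministically.
#' @return An object of class `ggm_experiment_spec`.
#' @export
experiment_spec <- function(graph = "random", p = 100L, n = "p/2",
                            n_true_edges = 30L, replicates = 30L,
                            methods = "dc", K = NULL, lambda = NULL,
                            zeta = NULL, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  rule <- NULL
  if (is.character(n)) {
    rule <- match.arg(n, c("p/2", "p", "2p"))
    n <- NULL
  }
  cells <- if (is.null(rule)) {
    tidyr::expand_grid(graph = graph, p = as.integer(p), n = as.integer(n))
  } else {
    f <- switch(rule, "p/2" = function(p) p %/% 2L, "p" = identity,
                "2p" = function(p) 2L * p)
    tidyr::expand_grid(graph = graph, p = as.integer(p)) |>
      dplyr::mutate(n = f(.data$p))
  }
  structure(list(cells = cells, n_true_edges = n_true_edges,
                 replicates = replicates, methods = methods, K = K,
                 lambda = lambda, zeta = zeta, seed = seed),
            class = "ggm_experiment_spec")
}

#' Run a replicate benchmark experiment
#'
#' For every cell and replicate: draw a ground truth, sample data, form the
#' shrunk sample covariance, run each method, and record edge-recovery
#' metrics, the selected edge count and solver diagnostics. Per-replicate
#' failures are caught and reported in the `error` column rather than
#' dropped. Results are fully reproducible from the spec's base seed.
#'
#' @param spec A [experiment_spec()] object.
#' @param verbose Print one line per cell as it completes.
#' @return A tidy tibble with one row per (cell, replicate, method):
#'   columns `graph`, `p`, `n`, `replicate`, `seed`, `method`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`, `n_edges`, `iterations` (outer DC
#'   iterations, or glasso sweeps), `n_eig` (DC only), `error`.
#' @export
run_experiment <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "ggm_experiment_spec"))
  out <- list()
  for (ci in seq_len(nrow(spec$cells))) {
    cell <- spec$cells[ci, ]
    for (r in seq_len(spec$replicates)) {
      # deterministic per-replicate seed, kept within 32-bit integer range
      seed_r <- (spec$seed * 10000L + ci * 1000L + r) %% .Machine$integer.max
      sim <- simulate_ggm(cell$graph, cell$p, cell$n,
                          n_true_edges = spec$n_true_edges,
                          zeta = spec$zeta, seed = seed_r)
      for (m in spec$methods) {
        row <- tibble::tibble(graph = cell$graph, p = cell$p, n = cell$n,
                              replicate = r, seed = seed_r, method = m)
        res <- tryCatch({
          fit <- switch(m,
            dc = dc_estimate(sim$S, K = spec$K %||% (cell$p * (cell$p - 1L) %/% 4L)),
            glasso = graphical_lasso(sim$S,
              lambda = spec$lambda %||% median_offdiag(sim$S$S)),
            adaptive = ggm_adaptive(sim$S,
              lambda = spec$lambda %||% median_offdiag(sim$S$S)),
            scad = ggm_scad(sim$S,
              lambda = spec$lambda %||% median_offdiag(sim$S$S)))
          conf <- edge_confusion(fit, sim$truth)
          dplyr::bind_cols(row, conf, tibble::tibble(
            n_edges = count_edges(fit),
            iterations = if (m == "dc") fit$dc_iterations else fit$iterations,
            n_eig = if (m == "dc") fit$n_eig else NA_integer_,
            error = NA_character_))
        }, error = function(e) {
          dplyr::bind_cols(row, tibble::tibble(
            tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
            precision = NA_real_, recall = NA_real_, f1 = NA_real_,
            n_edges = NA_integer_, iterations = NA_integer_,
            n_eig = NA_integer_, error = conditionMessage(e)))
        })
        out[[length(out) + 1L]] <- res
      }
    }
    if (verbose)
      message(sprintf("cell %d/%d done (%s, p=%d, n=%d)", ci,
                      nrow(spec$cells), cell$graph, cell$p, cell$n))
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

median_offdiag <- function(S) stats::median(abs(S[upper.tri(S)]))

#' Aggregate replicate results with 95% confidence intervals
#'
#' Mean and normal-approximation 95% confidence interval
#' (`mean +/- 1.96 * SE`) of each numeric metric, by cell and method.
#'
#' @param results Tibble from [run_experiment()].
#' @return A tibble with one row per (cell, method, metric).
#' @export
summarize_experiment <- function(results) {
  results |>
    dplyr::filter(is.na(.data$error)) |>
    tidyr::pivot_longer(c("precision", "recall", "f1", "n_edges",
                          "iterations", "n_eig"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$graph, .data$p, .data$n, .data$method, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci_lo = mean(.data$value) - 1.96 * stats::sd(.data$value) /
        sqrt(dplyr::n()),
      ci_hi = mean(.data$value) + 1.96 * stats::sd(.data$value) /
        sqrt(dplyr::n()),
      replicates = dplyr::n(), .groups = "drop")
}

#' Iteration/eigenvalue summary table for the DC algorithm
#'
#' Formats DC solver diagnostics as one row per (p, n) with the mean number
#' of outer iterations and smallest-eigenvalue computations for each graph
#' kind, rounded to one decimal.
#'
#' @param results Tibble from [run_experiment()] containing DC runs.
#' @return A tibble with columns `p`, `n` and, per graph kind present,
#'   `<graph>_ite` and `<graph>_eig`.
#' @export
report_iteration_table <- function(results) {
  dc <- dplyr::filter(results, .data$method == "dc", is.na(.data$error))
  if (nrow(dc) == 0)
    return(tibble::tibble(p = integer(), n = integer()))
  dc |>
    dplyr::group_by(.data$graph, .data$p, .data$n) |>
    dplyr::summarise(ite = round(mean(.data$iterations), 1),
                     eig = round(mean(.data$n_eig), 1), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "graph", values_from = c("ite", "eig"),
                       names_glue = "{graph}_{.value}") |>
    dplyr::arrange(.data$p, .data$n)
}
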
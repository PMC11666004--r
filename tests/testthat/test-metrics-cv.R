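test_that("edge confusion counts supports over unordered pairs", {
  est <- diag(3); est[1, 2] <- est[2, 1] <- 1; est[1, 3] <- est[3, 1] <- 1
  tru <- diag(3); tru[1, 2] <- tru[2, 1] <- 1; tru[2, 3] <- tru[3, 2] <- 1
  m <- edge_confusion(est, tru)
  expect_equal(unlist(m[c("tp", "fp", "fn")]), c(tp = 1, fp = 1, fn = 1))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)

  m2 <- edge_confusion(tru, tru)
  expect_equal(m2$f1, 1)
  m3 <- edge_confusion(diag(3), tru)
  expect_equal(m3$recall, 0)
  expect_equal(m3$f1, 0)
  expect_error(edge_confusion(diag(3), diag(4)), "same dimension")
})

test_that("F1 equals 2TP / (2TP + FP + FN) on random supports", {
  set.seed(50)
  for (r in 1:50) {
    p <- sample(4:10, 1)
    mk <- function() {
      M <- diag(p)
      pairs <- which(upper.tri(M), arr.ind = TRUE)
      sel <- sample(nrow(pairs), sample(0:nrow(pairs), 1))
      for (s in sel) M[pairs[s, 1], pairs[s, 2]] <- M[pairs[s, 2], pairs[s, 1]] <- 1
      M
    }
    est <- mk(); tru <- mk()
    m <- edge_confusion(est, tru)
    denom <- 2 * m$tp + m$fp + m$fn
    expect_equal(m$f1, if (denom == 0) 0 else 2 * m$tp / denom)
    expect_equal(m$tp + m$fn, count_edges(tru))   # tp+fn fixed by the truth
  }
})

test_that("count_edges reads the exact-zero support", {
  expect_equal(count_edges(diag(4)), 0)
  expect_equal(count_edges(matrix(1, 3, 3)), 3)
  set.seed(51)
  S <- random_pd(6)
  lam_max <- max(abs(S[upper.tri(S)]))
  expect_equal(count_edges(graphical_lasso(S, lam_max)), 0)
})

test_that("cardinality grid spans p+2 .. p^2", {
  g50 <- k_grid(50)
  expect_equal(g50[1], 52)
  expect_equal(g50[length(g50)], 2500)
  g10 <- k_grid(10)
  expect_equal(range(g10), c(12, 100))
  expect_true(all(g10 >= 12 & g10 <= 100))
  expect_false(is.unsorted(g10))
})

test_that("penalty grid ends where the glasso support empties", {
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  g <- lambda_grid(S)
  expect_equal(g[1], 0)
  expect_equal(g[length(g)], 0.8)
  expect_warning(lambda_grid(diag(3)), "degenerate")
  set.seed(52)
  Sp <- random_pd(5)
  gg <- lambda_grid(Sp)
  expect_equal(count_edges(graphical_lasso(Sp, gg[length(gg)])), 0)
})

test_that("cross-validation selects deterministically under a seed", {
  sim <- simulate_ggm("chain", p = 10, n = 50, n_true_edges = 10L, seed = 53)
  cv1 <- ggm_cv(sim$data, "dc", grid = c(14, 20, 30), seed = 9)
  cv2 <- ggm_cv(sim$data, "dc", grid = c(14, 20, 30), seed = 9)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_identical(cv1$selected, cv2$selected)
  expect_identical(cv1$curve, cv2$curve)
})

test_that("degenerate and duplicated grids behave sensibly", {
  sim <- simulate_ggm("chain", p = 8, n = 40, n_true_edges = 8L, seed = 54)
  cv1 <- ggm_cv(sim$data, "dc", grid = 16, seed = 1)
  expect_equal(cv1$selected, 16)
  cv2 <- ggm_cv(sim$data, "dc", grid = c(16, 16, 24), seed = 1)
  cv3 <- ggm_cv(sim$data, "dc", grid = c(16, 24), seed = 1)
  expect_identical(cv2$selected, cv3$selected)
})

test_that("held-out score equals the likelihood evaluated on the fold", {
  set.seed(55)
  x <- as.matrix(sample_ggm_data(make_chain_graph_precision(6, seed = 56), 60))
  cv <- ggm_cv(x, "glasso", grid = c(0.1, 0.3), folds = 3, seed = 2,
               zeta = 0.2)
  # recompute fold 1 by hand for the first grid value
  f <- 1
  S_tr <- shrink_covariance(sample_covariance(x[cv$fold_id != f, ]), 0.2)
  S_va <- sample_covariance(x[cv$fold_id == f, ])$S
  fit <- graphical_lasso(S_tr, 0.1)
  manual <- -neg_log_likelihood(fit$Omega, S_va)
  # reconstruct all folds to compare the mean
  scores <- vapply(1:3, function(f) {
    S_tr <- shrink_covariance(sample_covariance(x[cv$fold_id != f, ]), 0.2)
    S_va <- sample_covariance(x[cv$fold_id == f, ])$S
    -neg_log_likelihood(graphical_lasso(S_tr, 0.1)$Omega, S_va)
  }, numeric(1))
  expect_equal(cv$curve$mean_loglik[cv$curve$value == 0.1], mean(scores),
               tolerance = 1e-10)
  expect_equal(scores[1], manual)
})

test_that("tidy and glance methods return well-formed tibbles", {
  sim <- simulate_ggm("chain", p = 10, n = 80, n_true_edges = 10L, seed = 57)
  fit <- ggm_dc(sim$data, edges = 10)
  td <- tidy(fit)
  expect_true(all(c("node_i", "node_j", "precision", "partial_cor") %in%
                    names(td)))
  expect_true(all(td$node_i < td$node_j))
  gl <- glance(fit)
  expect_equal(gl$n_edges, count_edges(fit))
  expect_equal(gl$K, fit$K)
  cv <- ggm_cv(sim$data, "dc", grid = c(14, 30), seed = 1)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(nrow(tidy(cv)), 2)
})
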
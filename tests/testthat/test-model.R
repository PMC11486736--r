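test_that("edge embedding dimension follows the concatenation growth law", {
  set.seed(1)
  g <- random_graph(4, 5)
  params <- bgnn_params(5, n_layers = 3, hidden = 4, dropout = 0, seed = 2)
  st <- bgnn_state(g)
  expect_equal(ncol(st$E), 1L)
  for (l in 1:3) {
    d_e_before <- ncol(st$E)
    st <- graph_update_layer(st, params$layers[[l]])
    expect_equal(ncol(st$E), 2L * 4L + d_e_before)  # 2*d_v + previous d_e
    expect_equal(ncol(st$Vo), 4L)
  }
  expect_equal(ncol(st$E), 2 * 4 * 3 + 1)
})

test_that("mismatched state and layer dimensions raise a shape error", {
  g <- random_graph(3, 4, seed = 1)
  params <- bgnn_params(5, n_layers = 1, hidden = 4, seed = 1)  # wrong m1
  expect_error(graph_update_layer(bgnn_state(g), params$layers[[1]]),
               "dimension mismatch")
})

test_that("all-zero transforms produce all-zero embeddings", {
  g <- random_graph(4, 3, seed = 3)
  params <- bgnn_params(3, n_layers = 1, hidden = 4, dropout = 0, seed = 1)
  params$layers[[1]]$Wa[] <- 0
  params$layers[[1]]$Wb[] <- 0
  st <- graph_update_layer(bgnn_state(g), params$layers[[1]])
  expect_true(all(st$Vo == 0))
  expect_true(all(st$Vf == 0))
})

test_that("a zeroed head reduces to its bias for every pair", {
  g <- random_graph(4, 3, seed = 4)
  params <- bgnn_params(3, n_layers = 2, hidden = 4, dropout = 0, seed = 1)
  params$head$W1[] <- 0
  params$head$W2[] <- 0
  params$head$b2 <- 3.25
  st <- bgnn_forward(g, params)
  preds <- predict_pairs(st, cbind(c(1, 2, 4), c(1, 3, 2)), params$head)
  expect_equal(preds, rep(3.25, 3))
  expect_error(predict_pairs(st, cbind(9, 1), params$head), "out of range")
})

test_that("evaluation-mode forward passes are deterministic", {
  g <- random_graph(5, 4, seed = 6)
  params <- bgnn_params(4, hidden = 6, seed = 8)
  p1 <- predict_pairs(bgnn_forward(g, params), cbind(1:5, 1), params$head)
  p2 <- predict_pairs(bgnn_forward(g, params), cbind(1:5, 1), params$head)
  expect_identical(p1, p2)
})

test_that("vectorized forward equals the loop oracle on random graphs", {
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(2:5, 1); m1 <- sample(2:5, 1)
    g <- random_graph(n, m1, missing_frac = runif(1, 0, 0.4))
    n_layers <- sample(1:3, 1)
    params <- bgnn_params(m1, n_layers = n_layers, hidden = sample(2:6, 1),
                          dropout = 0)
    st <- bgnn_forward(g, params)
    orc <- oracle_forward(g, params)
    for (i in seq_len(n)) {
      expect_equal(st$Vo[i, ], orc$Vo[[i]], tolerance = 1e-5)
    }
    for (j in seq_len(m1)) {
      expect_equal(st$Vf[j, ], orc$Vf[[j]], tolerance = 1e-5)
    }
    i <- sample(n, 1); j <- sample(m1, 1)
    expect_equal(predict_pairs(st, cbind(i, j), params$head),
                 oracle_predict_pair(orc, i, j, params$head),
                 tolerance = 1e-5)
  }
})

test_that("compiled eval forward agrees with the R implementation", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:10, 1); m1 <- sample(3:6, 1)
    g <- random_graph(n, m1)
    params <- bgnn_params(m1, n_layers = 3, hidden = 8)
    pi <- sample(n, 4, replace = TRUE); pj <- sample(m1, 4, replace = TRUE)
    pr_r <- predict_pairs(bgnn_forward(g, params), cbind(pi, pj), params$head)
    pr_c <- bgyield:::cpp_bgnn_eval(unclass(params), g$weights, g$obs_init,
                                    pi, pj)
    expect_equal(drop(pr_c), pr_r, tolerance = 1e-9)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(31)
  n <- 4; m1 <- 3
  g <- random_graph(n, m1)
  params <- bgnn_params(m1, n_layers = 2, hidden = 5, dropout = 0)
  pi <- c(1L, 2L, 3L); pj <- c(3L, 1L, 2L); targ <- c(0.5, -0.2, 1.0)
  call_loss <- function(p) {
    bgyield:::cpp_bgnn_loss_grad(unclass(p), g$weights, g$obs_init,
                                 pi, pj, targ, 2L, 0.3, TRUE)
  }
  res <- call_loss(params)
  eps <- 1e-6
  for (case in list(
    list(\(p) p$layers[[1]]$Wa, \(p, v) { p$layers[[1]]$Wa[] <- v; p }, res$layers[[1]]$Wa),
    list(\(p) p$layers[[2]]$Wa, \(p, v) { p$layers[[2]]$Wa[] <- v; p }, res$layers[[2]]$Wa),
    list(\(p) p$layers[[2]]$Wb, \(p, v) { p$layers[[2]]$Wb[] <- v; p }, res$layers[[2]]$Wb),
    list(\(p) p$head$W1, \(p, v) { p$head$W1[] <- v; p }, res$head$W1))) {
    p0 <- case[[1]](params)
    idx <- sample(length(p0), min(5, length(p0)))
    for (k in idx) {
      pp <- p0; pp[k] <- p0[k] + eps
      up <- call_loss(case[[2]](params, pp))$loss
      pp[k] <- p0[k] - eps
      dn <- call_loss(case[[2]](params, pp))$loss
      expect_equal((up - dn) / (2 * eps), case[[3]][k], tolerance = 1e-5)
    }
  }
})

test_that("observation-row permutation permutes yield predictions identically", {
  set.seed(17)
  df <- tibble::as_tibble(as.data.frame(matrix(rnorm(36), 6)))
  names(df) <- c(paste0("f", 1:5), "yield")
  df$f2[3] <- NA
  perm <- sample(6)
  params <- bgnn_params(6, hidden = 8, seed = 9)
  g1 <- build_bipartite_graph(as_feature_table(df))
  g2 <- build_bipartite_graph(as_feature_table(df[perm, ]))
  p1 <- predict_pairs(bgnn_forward(g1, params), cbind(1:6, 6), params$head)
  p2 <- predict_pairs(bgnn_forward(g2, params), cbind(1:6, 6), params$head)
  expect_equal(p2, p1[perm], tolerance = 1e-9)
})

test_that("training-mode dropout zeroes about p of units, eval mode none", {
  set.seed(55)
  m <- bgyield:::dropout_mask(100, 100, 0.1)
  expect_gt(stats::binom.test(sum(m == 0), 1e4, 0.1)$p.value, 1e-4)
  expect_equal(unique(as.vector(m[m > 0])), 1 / 0.9, tolerance = 1e-12)

  g <- random_graph(6, 4, seed = 2)
  params <- bgnn_params(4, hidden = 8, dropout = 0.1, seed = 3)
  e1 <- bgnn_forward(g, params, training = FALSE)
  e2 <- bgnn_forward(g, params, training = FALSE)
  expect_identical(e1$Vo, e2$Vo)  # no stochasticity outside training
  set.seed(1); t1 <- bgnn_forward(g, params, training = TRUE)
  set.seed(2); t2 <- bgnn_forward(g, params, training = TRUE)
  expect_false(identical(t1$Vo, t2$Vo))
})

test_that("a table with no missing cells passes feature cells through", {
  df <- tibble::as_tibble(as.data.frame(matrix(rnorm(20), 4)))
  names(df) <- c(paste0("f", 1:4), "yield")
  g <- build_bipartite_graph(as_feature_table(df))
  params <- bgnn_params(5, hidden = 6, seed = 4)
  out <- bgnn_impute(g, params)
  expect_equal(unname(out$values[, 1:4]), unname(g$weights[, 1:4]))
  expect_length(out$yield, 4L)
})

test_that("checkpoints round-trip through JSON", {
  params <- bgnn_params(7, n_layers = 3, hidden = 5, dropout = 0.1, seed = 42)
  path <- withr::local_tempfile(fileext = ".json")
  write_bgnn(params, path)
  back <- read_bgnn(path)
  expect_equal(back$config$hidden, 5)
  expect_equal(back$config$seed, 42)
  for (l in 1:3) {
    expect_equal(back$layers[[l]]$Wa, params$layers[[l]]$Wa, tolerance = 1e-12)
    expect_equal(back$layers[[l]]$bb, params$layers[[l]]$bb, tolerance = 1e-12)
  }
  expect_equal(back$head$W2, params$head$W2, tolerance = 1e-12)
  # the restored parameters drive an identical forward pass
  g <- random_graph(4, 7, seed = 13)
  p1 <- predict_pairs(bgnn_forward(g, params), cbind(1:4, 7), params$head)
  p2 <- predict_pairs(bgnn_forward(g, back), cbind(1:4, 7), back$head)
  expect_equal(p1, p2, tolerance = 1e-10)
})
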
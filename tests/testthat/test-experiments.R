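complete_fixture <- function(n = 60, seed = 5) {
  sim <- simulate_trial_data(n_samples = n, n_weather = 5, n_traits = 5,
                             n_categorical = 1, missing_rate = 0, seed = seed)
  sim$table
}

test_that("deletion counts are binomially consistent with the rate", {
  x <- complete_fixture(n = 200)
  res <- imputation_experiment(x, rates = 0.2, methods = "mean", seed = 8)
  n_cells <- 200 * 10
  expect_lt(abs(res$n_deleted - 0.2 * n_cells), 4 * sqrt(n_cells * 0.2 * 0.8))
})

test_that("baseline MAEs match a closed-form oracle on the deletion pattern", {
  x <- complete_fixture(n = 80)
  seed <- 13
  res <- imputation_experiment(x, rates = c(0.1, 0.3),
                               methods = c("mean", "median"), seed = seed)
  xe <- encode_categoricals(x)
  feat <- ft_feature_names(xe)
  vals <- ft_values(xe)[, feat]
  sch <- ft_schema(xe)
  for (rate in c(0.1, 0.3)) {
    del <- apply_missingness(
      xe, rate = rate, mechanism = "MCAR",
      seed = bgyield:::seed_substream(seed, paste0("delete", rate)))$mask
    for (method in c("mean", "median")) {
      fun <- if (method == "mean") mean else stats::median
      err <- 0
      for (j in seq_along(feat)) {
        if (!any(del[, j])) next
        fill <- fun(vals[!del[, j], j])
        i <- match(feat[j], sch$name)
        if (sch$kind[i] == "categorical") {
          fill <- min(max(round(fill), 1), length(sch$label_map[[i]]))
        }
        err <- err + sum(abs(fill - vals[del[, j], j]))
      }
      oracle_mae <- err / sum(del)
      got <- res$mae[res$method == method & res$rate == rate]
      expect_equal(got, oracle_mae, tolerance = 1e-12)
    }
  }
})

test_that("mean imputation is exact for a constant column's deletions", {
  df <- tibble::tibble(flat = rep(5, 30) + 0, v = rnorm(30), yield = rnorm(30))
  # add noise column so normalization elsewhere is unaffected
  x <- as_feature_table(df)
  res <- imputation_experiment(x, rates = 0.3, methods = "mean", seed = 4)
  del <- apply_missingness(encode_categoricals(x), rate = 0.3,
                           seed = bgyield:::seed_substream(4, "delete0.3"))$mask
  imp <- baseline_impute(
    apply_missingness(encode_categoricals(x), rate = 0.3,
                      seed = bgyield:::seed_substream(4, "delete0.3"))$table,
    "mean")
  expect_true(all(abs(imp$flat - 5) < 1e-12))
})

test_that("a repeated seed reproduces deletions and MAEs exactly", {
  x <- complete_fixture(n = 50)
  r1 <- imputation_experiment(x, rates = 0.2, methods = c("mean", "knn"),
                              seed = 99)
  r2 <- imputation_experiment(x, rates = 0.2, methods = c("mean", "knn"),
                              seed = 99)
  expect_identical(r1$mae, r2$mae)
  expect_identical(r1$n_deleted, r2$n_deleted)
})

test_that("invalid rates and incomplete inputs are rejected", {
  x <- complete_fixture(n = 20)
  expect_error(imputation_experiment(x, rates = 1.2), "rates")
  xm <- apply_missingness(x, 0.2, seed = 1)$table
  expect_error(imputation_experiment(xm, rates = 0.1), "complete")
})

test_that("the experiment result plots as MAE against rate", {
  x <- complete_fixture(n = 40)
  res <- imputation_experiment(x, rates = c(0.1, 0.2), methods = "mean",
                               seed = 3)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("a single-cell ablation grid yields one metrics row", {
  x <- simulate_trial_data(n_samples = 50, n_weather = 4, n_traits = 4,
                           n_categorical = 0, missing_rate = 0.1,
                           seed = 17)$table
  grid <- tibble::tibble(dropout = TRUE, n_layers = 2L, loss = "ghm",
                         alpha = 0.3)
  res <- ablation(x, grid = grid, epochs = 15, hidden = 8,
                  test_rows = 1:10, seed = 6)
  expect_equal(nrow(res), 1L)
  expect_true(is.finite(res$mae))
  expect_equal(res$epochs_run, 15)
})

test_that("the default grid enumerates the 8 unique configurations", {
  grid <- default_ablation_grid()
  expect_equal(nrow(grid), 8L)
  expect_equal(nrow(dplyr::distinct(grid)), 8L)
  expect_setequal(unique(grid$n_layers), c(2L, 3L, 4L))
  expect_setequal(unique(grid$loss), c("ghm", "l1", "l2"))
  expect_setequal(grid$alpha[grid$loss == "ghm"], c(0.3, 0.5, 0.7))
})

test_that("all ablation rows share one split (controlled comparison)", {
  x <- simulate_trial_data(n_samples = 40, n_weather = 4, n_traits = 4,
                           n_categorical = 0, missing_rate = 0.1,
                           seed = 23)$table
  grid <- default_ablation_grid()[c(1, 5), ]
  res <- ablation(x, grid = grid, epochs = 10, hidden = 6,
                  test_rows = c(3, 7, 11, 15), seed = 2)
  expect_equal(nrow(res), 2L)
  # both rows were evaluated on the same 4 test observations
  expect_true(all(is.finite(res$mae)))
  expect_s3_class(autoplot(res), "ggplot")
})
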
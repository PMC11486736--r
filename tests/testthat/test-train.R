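test_that("rows split by missing-feature count: <=1 trains, >=2 tests", {
  ft <- missingness_table(counts = c(0, 1, 2, 3))
  sp <- split_by_missingness(ft)
  expect_equal(sp$train, c(1L, 2L))
  expect_equal(sp$test, c(3L, 4L))
})

test_that("a complete table goes entirely to train, with a warning", {
  ft <- missingness_table(counts = c(0, 0, 0))
  expect_warning(sp <- split_by_missingness(ft), "empty test")
  expect_equal(sp$train, 1:3)
  expect_length(sp$test, 0L)
})

test_that("the split counts feature columns only, never the yield", {
  ft <- missingness_table(counts = c(0, 1))
  data <- tibble::as_tibble(ft)
  data$yield[1] <- NA  # missing yield must not push row 1 to test
  ft2 <- bgyield:::ft_replace_data(ft, data)
  expect_warning(sp <- split_by_missingness(ft2), "empty test")
  expect_equal(sp$train, c(1L, 2L))
  # oracle: per-row loop count over feature columns
  mask <- ft_mask(ft2)
  for (i in seq_len(nrow(ft2))) {
    cnt <- 0
    for (nm in ft_feature_names(ft2)) cnt <- cnt + is.na(data[[nm]][i])
    expect_equal(cnt, sum(!mask[i, ft_feature_names(ft2)]))
  }
})

train_fixture <- function(n = 60, seed = 7) {
  simulate_trial_data(n_samples = n, n_weather = 6, n_traits = 4,
                      n_categorical = 1, n_groups = 3,
                      missing_rate = 0.1, seed = seed)$table
}

test_that("identically seeded runs produce identical results", {
  x <- train_fixture()
  f1 <- train_bgnn(x, epochs = 30, hidden = 8, test_rows = 1:10, seed = 42)
  f2 <- train_bgnn(x, epochs = 30, hidden = 8, test_rows = 1:10, seed = 42)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params$layers[[1]]$Wa, f2$params$layers[[1]]$Wa)
  expect_identical(predict(f1)$yield_pred, predict(f2)$yield_pred)
})

test_that("training reduces the loss on a small synthetic table", {
  x <- simulate_trial_data(n_samples = 100, n_weather = 5, n_traits = 5,
                           n_categorical = 0, missing_rate = 0.1,
                           seed = 3)$table
  fit <- train_bgnn(x, epochs = 200, hidden = 16, test_rows = 1:20, seed = 1,
                    patience = 0)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
})

test_that("lambda = 0 makes the feature-reconstruction term exactly zero", {
  x <- train_fixture()
  fit <- train_bgnn(x, epochs = 20, hidden = 8, lambda = 0,
                    test_rows = 1:10, seed = 2)
  expect_true(all(fit$history$feature_loss == 0))
  expect_equal(fit$history$loss, fit$history$yield_loss)
})

test_that("training without any supervised yield is an error", {
  df <- tibble::tibble(a = rnorm(5), b = rnorm(5), yield = rep(NA_real_, 5))
  expect_error(
    suppressWarnings(train_bgnn(as_feature_table(df), epochs = 5,
                                test_rows = integer())),
    "observed yield")
})

test_that("test-row yield edges never enter the graph or supervision", {
  x <- train_fixture()
  fit <- train_bgnn(x, epochs = 10, hidden = 8, test_rows = c(2, 5, 9), seed = 1)
  g <- fit$graph
  expect_true(all(g$weights[c(2, 5, 9), g$m1] == 0))
  expect_true(all(!g$supervised[c(2, 5, 9), g$m1]))
  expect_true(all(g$obs_init[c(2, 5, 9), g$m1] == 0))
})

test_that("early stopping halts on a training-loss plateau", {
  x <- train_fixture(n = 40)
  fit <- train_bgnn(x, epochs = 2000, hidden = 4, lr = 0, patience = 10,
                    test_rows = 1:8, seed = 1)
  expect_lt(fit$epochs_run, 2000)  # lr 0 cannot improve, stops at patience
})

test_that("the trait-only variant drops the yield node entirely", {
  x <- train_fixture()
  fit <- train_bgnn(x, target = NULL, epochs = 20, hidden = 8, seed = 4)
  expect_false(fit$graph$has_yield)
  expect_equal(fit$graph$m1, length(ft_feature_names(x)))
  expect_true(all(fit$history$yield_loss == 0))
  expect_error(predict(fit), "no yield node")
})

test_that("imputed tables keep observed cells and fill missing ones", {
  x <- train_fixture()
  fit <- train_bgnn(x, epochs = 20, hidden = 8, test_rows = 1:10, seed = 5)
  imp <- impute_missing(fit)
  feat <- ft_feature_names(x)
  obs <- !is.na(as.matrix(x[, feat]))
  xi <- as.matrix(tibble::as_tibble(imp)[, feat])
  xo <- as.matrix(tibble::as_tibble(x)[, feat])
  expect_equal(xi[obs], xo[obs])
  expect_false(anyNA(xi))
  # categorical imputations are valid labels
  sch <- ft_schema(imp)
  cat_cols <- sch$name[sch$kind == "categorical" & sch$name %in% feat]
  for (nm in cat_cols) {
    expect_true(all(imp[[nm]] %in% seq_along(sch$label_map[[match(nm, sch$name)]])))
  }
})

test_that("tidy and glance summarize the fit", {
  x <- train_fixture()
  fit <- train_bgnn(x, epochs = 15, hidden = 8, test_rows = 1:10, seed = 6)
  td <- tidy(fit)
  expect_equal(names(td), c("epoch", "loss", "yield_loss", "feature_loss"))
  expect_equal(nrow(td), fit$epochs_run)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(is.finite(gl$test_mae))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
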
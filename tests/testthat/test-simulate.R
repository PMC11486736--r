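test_that("the same seed reproduces the table bit for bit", {
  s1 <- simulate_trial_data(n_samples = 40, seed = 9)
  s2 <- simulate_trial_data(n_samples = 40, seed = 9)
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))
  expect_identical(s1$truth$deletion_mask, s2$truth$deletion_mask)
})

test_that("rho = 0 decouples the weather and trait blocks", {
  sim <- simulate_trial_data(n_samples = 2000, n_weather = 6, n_traits = 6,
                             n_categorical = 0, rho = 0, rho_weather = 0,
                             missing_rate = 0, seed = 21)
  vals <- ft_values(sim$table)
  cors <- abs(stats::cor(vals[, 1:6], vals[, 7:12]))
  expect_lt(mean(cors), 0.1)
  expect_lt(max(cors), 0.12)
})

test_that("power-law group sizes are sorted descending and cover all rows", {
  sim <- simulate_trial_data(n_samples = 200, n_groups = 5, group_skew = 1.5,
                             seed = 2)
  sizes <- as.integer(table(factor(ft_groups(sim$table),
                                   levels = sprintf("loc_%02d", 1:5))))
  expect_equal(sum(sizes), 200L)
  expect_true(all(diff(sizes) <= 0))
  expect_gt(sizes[1], sizes[5])
})

test_that("rate 0 deletes nothing", {
  sim <- simulate_trial_data(n_samples = 20, missing_rate = 0, seed = 1)
  out <- apply_missingness(sim$table, rate = 0)
  expect_identical(as.data.frame(out$table), as.data.frame(sim$table))
  expect_false(any(out$mask))
})

test_that("the realized MCAR deletion fraction concentrates near the rate", {
  sim <- simulate_trial_data(n_samples = 2500, n_weather = 20, n_traits = 20,
                             n_categorical = 0, missing_rate = 0, seed = 31)
  out <- apply_missingness(sim$table, rate = 0.18, seed = 5)
  expect_equal(mean(out$mask), 0.18, tolerance = 0.01 / 0.18)  # 1e5 cells
})

test_that("invalid deletion rates are rejected and yield is never deleted", {
  sim <- simulate_trial_data(n_samples = 20, missing_rate = 0, seed = 1)
  expect_error(apply_missingness(sim$table, rate = 1), "rate")
  out <- apply_missingness(sim$table, rate = 0.5, seed = 2)
  expect_false(anyNA(out$table$yield))
  expect_false("yield" %in% colnames(out$mask))
})

test_that("MNAR deletion targets larger values; MCAR does not", {
  sim <- simulate_trial_data(n_samples = 1500, n_weather = 8, n_traits = 8,
                             n_categorical = 0, missing_rate = 0, seed = 41)
  vals <- ft_values(sim$table)[, ft_feature_names(sim$table)]
  mnar <- apply_missingness(sim$table, rate = 0.2, mechanism = "MNAR",
                            strength = 3, seed = 6)
  expect_gt(mean(vals[mnar$mask]), mean(vals[!mnar$mask]))
  expect_equal(mean(mnar$mask), 0.2, tolerance = 0.1)

  # chi-square independence of deletion and cell sign: MCAR passes,
  # MNAR fails, in a majority of seeds
  verdicts <- vapply(1:5, function(s) {
    mc <- apply_missingness(sim$table, rate = 0.2, mechanism = "MCAR", seed = s)
    mn <- apply_missingness(sim$table, rate = 0.2, mechanism = "MNAR",
                            strength = 3, seed = s)
    p_mc <- stats::chisq.test(table(vals > 0, mc$mask))$p.value
    p_mn <- stats::chisq.test(table(vals > 0, mn$mask))$p.value
    c(p_mc > 0.01, p_mn < 0.01)
  }, logical(2))
  expect_gte(sum(verdicts[1, ]), 3)
  expect_gte(sum(verdicts[2, ]), 3)
})

test_that("closed-form true R^2 matches the empirical signal fraction", {
  sim <- simulate_trial_data(n_samples = 5000, missing_rate = 0,
                             target_r2 = 0.8, seed = 51)
  y <- sim$table$yield
  s <- sim$truth$signal
  r2_emp <- 1 - sum((y - s)^2) / sum((y - mean(y))^2)
  expect_equal(sim$truth$true_r2, 0.8, tolerance = 1e-9)  # calibrated
  expect_equal(r2_emp, sim$truth$true_r2, tolerance = 0.05)
})

test_that("an explicit sigma_y overrides the calibration", {
  sim <- simulate_trial_data(n_samples = 3000, missing_rate = 0,
                             sigma_y = 10, seed = 61)
  expect_lt(sim$truth$true_r2, 0.2)  # large noise, low signal fraction
  y <- sim$table$yield; s <- sim$truth$signal
  r2_emp <- 1 - sum((y - s)^2) / sum((y - mean(y))^2)
  expect_equal(r2_emp, sim$truth$true_r2, tolerance = 0.08)
})

test_that("fixtures round-trip through disk and regenerate from config", {
  sim <- simulate_trial_data(n_samples = 25, seed = 77)
  dir <- withr::local_tempdir()
  write_fixture(sim$table, sim$truth, dir)
  expect_setequal(list.files(dir), c("table.csv", "truth.csv", "config.yaml"))

  cfg <- ft_schema(sim$table)
  cats <- cfg$name[cfg$kind == "categorical"]
  back <- read_feature_table(file.path(dir, "table.csv"),
                             group_col = "location", categorical = cats)
  expect_equal(ft_values(back), ft_values(encode_categoricals(sim$table)))
  expect_equal(ft_mask(back), ft_mask(sim$table))

  sim2 <- do.call(simulate_trial_data, read_sim_config(dir))
  expect_identical(as.data.frame(sim2$table), as.data.frame(sim$table))
})
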
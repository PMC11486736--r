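#' Random-deletion imputation benchmark
#'
#' The standard protocol for judging imputation quality when truth is known:
#' start from rows with no missing feature data, delete feature cells
#' completely at random at each requested rate, impute with each method, and
#' report the mean absolute error between imputed and held-out true values
#' over the deleted cells only, in original units. The network runs in its
#' trait-only variant (the yield feature node is removed, only the
#' self-supervised reconstruction loss is optimized), so the comparison is
#' purely about imputation.
#'
#' @param x A [feature_table][as_feature_table] whose feature columns are
#'   complete (filter to complete rows first).
#' @param rates Deletion rates (default `c(0.1, 0.2, 0.3)`).
#' @param methods Any of `"mean"`, `"median"`, `"knn"`, `"bgnn"`.
#' @param k Neighbours for the knn baseline (default 5).
#' @param epochs,hidden,n_layers,dropout Network settings for the `"bgnn"`
#'   method (defaults 200, 32, 3, 0.1 — reduced scale for benchmarking).
#' @param seed Master seed; per-rate deletion patterns and network training
#'   draw from named substreams of it.
#' @return An `imputation_experiment` tibble: `method`, `rate`, `mae`,
#'   `n_deleted`. Has an [ggplot2::autoplot()] method (MAE against rate, one
#'   line per method).
#' @export
imputation_experiment <- function(x, rates = c(0.1, 0.2, 0.3),
                                  methods = c("mean", "median", "knn", "bgnn"),
                                  k = 5, epochs = 200, hidden = 32,
                                  n_layers = 3, dropout = 0.1, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (any(rates <= 0 | rates >= 1)) stop("rates must be in (0, 1)", call. = FALSE)
  x <- encode_categoricals(if (inherits(x, "feature_table")) x else as_feature_table(x))
  feat <- ft_feature_names(x)
  if (anyNA(x[feat])) {
    stop("imputation benchmark needs complete feature rows; filter first",
         call. = FALSE)
  }
  truth_vals <- ft_values(x)[, feat, drop = FALSE]
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)

  res <- purrr::map_dfr(rates, function(rate) {
    del <- apply_missingness(x, rate = rate, mechanism = "MCAR",
                             seed = seed_substream(seed, paste0("delete", rate)))
    deleted <- del$mask
    purrr::map_dfr(methods, function(method) {
      imp <- if (method == "bgnn") {
        fit <- train_bgnn(del$table, target = NULL, epochs = epochs,
                          hidden = hidden, n_layers = n_layers,
                          dropout = dropout,
                          seed = seed_substream(seed, paste0("net", rate)))
        impute_missing(fit)
      } else {
        baseline_impute(del$table, method = method, k = k)
      }
      imp_vals <- ft_values(imp)[, feat, drop = FALSE]
      tibble::tibble(
        method = method, rate = rate,
        mae = mean(abs(imp_vals[deleted] - truth_vals[deleted])),
        n_deleted = sum(deleted)
      )
    })
  })
  class(res) <- c("imputation_experiment", class(res))
  res
}

#' @export
autoplot.imputation_experiment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rate, y = .data$mae,
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(object$rate)) +
    ggplot2::labs(x = "deletion rate", y = "imputation MAE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Default ablation grid
#'
#' The eight unique configurations of the standard ablation: dropout on/off,
#' 2/3/4 update layers, and L1 / L2 / gradient-harmonized loss with alpha in
#' 0.3 / 0.5 / 0.7, sharing the full default configuration as the common
#' baseline row.
#'
#' @return A tibble with columns `dropout`, `n_layers`, `loss`, `alpha`.
#' @export
default_ablation_grid <- function() {
  tibble::tribble(
    ~dropout, ~n_layers, ~loss, ~alpha,
    TRUE,  3L, "ghm", 0.3,   # full configuration (shared baseline)
    FALSE, 3L, "ghm", 0.3,
    TRUE,  2L, "ghm", 0.3,
    TRUE,  4L, "ghm", 0.3,
    TRUE,  3L, "l1",  NA,
    TRUE,  3L, "l2",  NA,
    TRUE,  3L, "ghm", 0.5,
    TRUE,  3L, "ghm", 0.7
  )
}

#' Ablation harness
#'
#' Trains one network per grid row with a shared seed and an identical
#' train/test split, and reports test-row yield metrics per configuration —
#' the controlled comparison isolating the effect of dropout, depth and loss
#' choice.
#'
#' @param x A [feature_table][as_feature_table].
#' @param grid A tibble like [default_ablation_grid()].
#' @param epochs,hidden Network settings shared by all runs (defaults 200,
#'   32).
#' @param test_rows Explicit test rows; `NULL` uses
#'   [split_by_missingness()].
#' @param seed Shared seed for every run.
#' @param verbose Print one line per configuration.
#' @return A `bgnn_ablation` tibble: the grid columns plus `mae`, `rmse`,
#'   `r2`, `final_loss`, `epochs_run`.
#' @export
ablation <- function(x, grid = default_ablation_grid(), epochs = 200,
                     hidden = 32, test_rows = NULL, seed = NULL,
                     verbose = FALSE) {
  x <- encode_categoricals(if (inherits(x, "feature_table")) x else as_feature_table(x))
  if (is.null(test_rows)) test_rows <- split_by_missingness(x)$test
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)

  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    fit <- train_bgnn(
      x, epochs = epochs, hidden = hidden,
      loss = g$loss, alpha = if (is.na(g$alpha)) 0.3 else g$alpha,
      n_layers = g$n_layers, dropout = if (g$dropout) 0.1 else 0,
      test_rows = test_rows, seed = seed
    )
    gl <- glance(fit)
    if (verbose) {
      message(sprintf("ablation %d/%d: %s -> test MAE %.3f", i, nrow(grid),
                      ablation_label(g), gl$test_mae))
    }
    dplyr::bind_cols(g, tibble::tibble(
      mae = gl$test_mae, rmse = gl$test_rmse, r2 = gl$test_r2,
      final_loss = gl$final_loss, epochs_run = gl$epochs_run
    ))
  })
  class(res) <- c("bgnn_ablation", class(res))
  res
}

ablation_label <- function(g) {
  sprintf("%d layers, dropout %s, %s%s",
          g$n_layers, if (g$dropout) "on" else "off", g$loss,
          if (g$loss == "ghm") sprintf("(%.1f)", g$alpha) else "")
}

#' @export
autoplot.bgnn_ablation <- function(object, ...) {
  object$label <- vapply(seq_len(nrow(object)),
                         function(i) ablation_label(object[i, ]), character(1))
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$label, .data$mae),
                                       y = .data$mae)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "test yield MAE") +
    ggplot2::theme_minimal()
}

# deterministic substream seed derived from a master seed and a name
seed_substream <- function(seed, name) {
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
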
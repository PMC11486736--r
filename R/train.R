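#' Split rows by their missing-feature count
#'
#' Rows with at most one missing feature form the training partition; rows
#' with two or more missing features form the test partition. The count is
#' taken over feature columns only — a missing yield never moves a row to
#' test. This mirrors how real trial tables concentrate missingness in a
#' subset of records; under uniform cell-level missingness with many columns
#' almost every row lands in test, in which case supply an explicit split to
#' [train_bgnn()] instead.
#'
#' @param x A [feature_table][as_feature_table].
#' @return A list with integer vectors `train` and `test` (a disjoint,
#'   exhaustive partition of the rows). An empty partition raises a warning,
#'   not an error.
#' @examples
#' ft <- as_feature_table(tibble::tibble(a = c(1, NA, NA), b = c(1, 2, NA),
#'                                       c = c(1, 1, 1), yield = c(5, 6, 7)))
#' split_by_missingness(ft)  # train: rows 1-2; test: row 3
#' @export
split_by_missingness <- function(x) {
  mask <- ft_mask(x)
  feat <- ft_feature_names(x)
  n_missing <- rowSums(!mask[, feat, drop = FALSE])
  train <- which(n_missing <= 1)
  test <- which(n_missing >= 2)
  if (length(train) == 0L) warning("empty training partition", call. = FALSE)
  if (length(test) == 0L) warning("empty test partition", call. = FALSE)
  list(train = train, test = test)
}

#' Train the bipartite graph network
#'
#' End-to-end pipeline: encode categorical traits, fit z-score parameters on
#' the training rows only, build the bipartite graph with test-row yields
#' forcibly hidden, and optimize the network with Adam on a gradient-
#' harmonized (or plain L1/L2) loss. The total loss is the yield loss over
#' training rows plus `lambda` times a self-supervised reconstruction loss
#' over a random fraction (`rehide_rate`) of observed feature cells that is
#' re-hidden from the input each epoch — the mechanism by which the network
#' learns to impute. Additionally, each epoch a random fraction
#' (`yield_hide_frac`) of training-row yield edges is hidden from the input
#' graph (supervision is unchanged): training rows otherwise carry their own
#' yield on an incident edge while evaluation rows carry zero, and the
#' network would learn to copy rather than predict. Set `yield_hide_frac = 0`
#' to disable.
#'
#' @param data A data frame or `feature_table` of observations; see
#'   [as_feature_table()] for column conventions.
#' @param epochs Maximum training epochs (default 500; raise towards 20000
#'   for a full-scale run).
#' @param loss `"ghm"` (default), `"l1"` or `"l2"`.
#' @param alpha Gradient-harmonizing constant for `loss = "ghm"`
#'   (default 0.3).
#' @param variant Harmonizing-term variant, `"absolute"` (default) or
#'   `"signed"`; see [ghm_loss()]. Training defaults to the absolute variant
#'   because the signed per-sample loss is minimized at a *negative*
#'   residual, \eqn{d^\ast = -\sqrt{\alpha^{4/3} - \alpha^2}} (about
#'   \eqn{-0.33} standardized units at \eqn{\alpha = 0.3}), so optimizing it
#'   converges to a systematic under-prediction bias.
#' @param lambda Weight of the feature-reconstruction term (default 1; 0
#'   disables it exactly).
#' @param rehide_rate Per-epoch probability that an observed feature cell is
#'   re-hidden and supervised (default 0.1).
#' @param yield_hide_frac Per-epoch probability that a training-row yield
#'   edge is hidden from the input (default 0.5).
#' @param lr Adam learning rate (default 1e-3).
#' @param n_layers,hidden,dropout Network architecture; see [bgnn_params()].
#' @param test_rows Rows whose yield is hidden and on which the fit is
#'   evaluated. `NULL` (default) uses [split_by_missingness()].
#' @param target `"yield"` (default) or `NULL` for the trait-only variant:
#'   the yield column is dropped from the graph entirely and only the
#'   reconstruction loss is optimized (pure imputation).
#' @param patience Early-stopping patience on the training-loss plateau
#'   (epochs without relative improvement > 1e-4; default 100; `0` disables).
#' @param seed Integer seed governing initialization, re-hiding and dropout.
#' @param verbose Print progress every 50 epochs.
#' @inheritParams as_feature_table
#' @return A `bgnn_fit` object; see [predict.bgnn_fit()], [impute_missing()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#'   methods.
#' @export
train_bgnn <- function(data, epochs = 500, loss = c("ghm", "l1", "l2"),
                       alpha = 0.3, variant = c("absolute", "signed"),
                       lambda = 1, rehide_rate = 0.1, yield_hide_frac = 0.5,
                       lr = 1e-3, n_layers = 3, hidden = 64, dropout = 0.1,
                       test_rows = NULL, target = "yield", patience = 100,
                       seed = NULL, verbose = FALSE,
                       yield_col = NULL, group_col = NULL, categorical = NULL) {
  loss <- match.arg(loss)
  variant <- match.arg(variant)
  stopifnot(epochs >= 1, lambda >= 0, rehide_rate >= 0, rehide_rate < 1,
            yield_hide_frac >= 0, yield_hide_frac <= 1)
  x <- if (inherits(data, "feature_table")) data else {
    as_feature_table(data, yield_col = yield_col, group_col = group_col,
                     categorical = categorical)
  }
  x <- encode_categoricals(x)
  include_yield <- !is.null(target)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(test_rows)) {
    split <- if (include_yield) split_by_missingness(x) else
      list(train = seq_len(nrow(x)), test = integer())
  } else {
    test_rows <- as.integer(test_rows)
    split <- list(train = setdiff(seq_len(nrow(x)), test_rows), test = test_rows)
  }

  yc <- attr(x, "yield_col")
  if (include_yield &&
      !any(!is.na(x[[yc]][split$train]))) {
    stop("no training row has an observed yield; nothing to supervise",
         call. = FALSE)
  }

  norm <- fit_normalizer(x, fit_rows = split$train)
  xn <- apply_normalizer(x, norm)
  graph <- build_bipartite_graph(xn, hide_yield_for = split$test,
                                 include_yield = include_yield)

  vals <- ft_values(xn)
  if (include_yield) {
    yobs <- split$train[!is.na(vals[split$train, yc])]
    ytarget <- vals[yobs, yc]
  } else {
    yobs <- integer(); ytarget <- numeric()
  }
  # observed feature cells (any row) available for per-epoch re-hiding
  sup <- graph$supervised
  if (include_yield) sup[, graph$m1] <- FALSE
  fcells <- which(sup, arr.ind = TRUE)
  dimnames(fcells) <- NULL
  fvalues <- graph$weights[fcells]
  use_rehide <- lambda > 0 && rehide_rate > 0 && nrow(fcells) > 0
  if (!use_rehide) {
    fcells <- matrix(integer(), 0, 2)
    fvalues <- numeric()
  }

  params <- bgnn_params(graph$m1, n_layers = n_layers, hidden = hidden,
                        dropout = dropout)
  fit_core <- cpp_bgnn_train(
    unclass(params), graph$weights, graph$obs_init,
    as.integer(yobs), ytarget,
    matrix(as.integer(fcells), ncol = 2L), fvalues,
    rehide_rate, if (include_yield) yield_hide_frac else 0,
    as.integer(epochs), lr, lambda,
    loss_kind_code(loss), alpha, variant == "signed",
    as.integer(patience), 1e-4, isTRUE(verbose)
  )
  params$layers <- purrr::map(fit_core$layers, function(l) {
    list(Wa = l$Wa, ba = as.numeric(l$ba), Wb = l$Wb, bb = as.numeric(l$bb),
         p = l$p)
  })
  params$head <- list(W1 = fit_core$head$W1, b1 = as.numeric(fit_core$head$b1),
                      W2 = matrix(as.numeric(fit_core$head$W2), ncol = 1L),
                      b2 = as.numeric(fit_core$head$b2))

  structure(list(
    params = params,
    graph = graph,
    norm = norm,
    table = x,             # encoded, original units
    split = split,
    history = tibble::as_tibble(fit_core$history),
    epochs_run = fit_core$epochs_run,
    config = list(epochs = epochs, loss = loss, alpha = alpha,
                  variant = variant, lambda = lambda,
                  rehide_rate = rehide_rate, yield_hide_frac = yield_hide_frac,
                  lr = lr, n_layers = n_layers, hidden = hidden,
                  dropout = dropout, patience = patience, seed = seed,
                  target = target)
  ), class = "bgnn_fit")
}

#' @export
print.bgnn_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "# bgnn_fit: %d epochs run (max %d), loss %s%s | %d train / %d test rows\n",
    x$epochs_run, cfg$epochs, cfg$loss,
    if (cfg$loss == "ghm") sprintf("(alpha=%.2f)", cfg$alpha) else "",
    length(x$split$train), length(x$split$test)))
  cat(sprintf("  final training loss: %.5f\n",
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Predict yield for rows of the fitted table
#'
#' Transductive prediction: the fitted graph already contains every row, so
#' prediction decodes the yield cell of the requested rows and inverts the
#' z-score transform back to original units (kg/acre for real trial data).
#'
#' @param object A `bgnn_fit`.
#' @param rows `"test"` (default), `"train"`, `"all"`, or an integer vector.
#' @param ... Unused.
#' @return A tibble: `.row`, `group`, `yield_true` (NA where unobserved) and
#'   `yield_pred`, in original units.
#' @export
predict.bgnn_fit <- function(object, rows = c("test", "train", "all"), ...) {
  if (is.character(rows)) {
    rows <- match.arg(rows)
    idx <- switch(rows, test = object$split$test, train = object$split$train,
                  all = seq_len(object$graph$n))
  } else idx <- as.integer(rows)
  if (!object$graph$has_yield) stop("trait-only fit has no yield node", call. = FALSE)
  if (length(idx) == 0L) stop("no rows to predict", call. = FALSE)

  state <- bgnn_forward(object$graph, object$params, training = FALSE)
  pred_z <- predict_pairs(state, cbind(idx, object$graph$m1), object$params$head)
  yc <- attr(object$table, "yield_col")
  pr <- object$norm[object$norm$column == yc, ]
  pred <- pred_z * pr$sigma + pr$mu
  tibble::tibble(
    .row = idx,
    group = ft_groups(object$table)[idx],
    yield_true = ft_values(object$table)[idx, yc],
    yield_pred = pred
  )
}

#' Impute the missing cells of the fitted table
#'
#' Decodes every missing feature cell from the final node embeddings, maps
#' values back to original units, and rounds categorical imputations to the
#' nearest valid label of the column's label map. Observed cells pass
#' through unchanged.
#'
#' @param fit A `bgnn_fit`.
#' @return A `feature_table` with no missing feature cells, in original
#'   units (still label-encoded; use [decode_categoricals()] for text
#'   labels).
#' @export
impute_missing <- function(fit) {
  stopifnot(inherits(fit, "bgnn_fit"))
  out <- bgnn_impute(fit$graph, fit$params)
  sch <- ft_schema(fit$table)
  data <- tibble::as_tibble(fit$table)
  vals_z <- out$values
  for (nm in fit$graph$feat_names) {
    pr <- fit$norm[fit$norm$column == nm, ]
    col_orig <- vals_z[, nm] * pr$sigma + pr$mu
    i <- match(nm, sch$name)
    if (sch$kind[i] == "categorical") {
      n_lab <- length(sch$label_map[[i]])
      col_orig <- pmin(pmax(round(col_orig), 1), max(n_lab, 1))
    }
    miss <- is.na(data[[nm]])
    if (nm == attr(fit$table, "yield_col")) {
      # yield stays NA where unobserved unless predicted explicitly
      next
    }
    data[[nm]][miss] <- col_orig[miss]
  }
  new_feature_table(data, sch, attr(fit$table, "yield_col"),
                    attr(fit$table, "group_col"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fit
#'
#' One row per epoch with the total, yield and feature-reconstruction loss.
#'
#' @param x A `bgnn_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `loss`, `yield_loss`,
#'   `feature_loss`.
#' @export
tidy.bgnn_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' Test-row yield metrics (original units) next to the training
#' configuration.
#'
#' @param x A `bgnn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `epochs_run`, `final_loss`, and — when test
#'   rows with observed yield exist — `test_mae`, `test_rmse`, `test_r2`.
#' @export
glance.bgnn_fit <- function(x, ...) {
  out <- tibble::tibble(
    epochs_run = x$epochs_run,
    final_loss = x$history$loss[nrow(x$history)],
    loss = x$config$loss,
    n_layers = x$config$n_layers,
    test_mae = NA_real_, test_rmse = NA_real_, test_r2 = NA_real_
  )
  if (x$graph$has_yield && length(x$split$test) > 0) {
    pr <- predict(x, rows = "test")
    pr <- pr[!is.na(pr$yield_true), ]
    if (nrow(pr) >= 2) {
      m <- compute_metrics(pr$yield_pred, pr$yield_true)
      out$test_mae <- m$mae[1]; out$test_rmse <- m$rmse[1]; out$test_r2 <- m$r2[1]
    }
  }
  out
}

#' Plot the training loss curve
#'
#' @param object A `bgnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bgnn_fit <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(object$history, -"epoch",
                                   names_to = "component", values_to = "value")
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss", colour = NULL) +
    ggplot2::theme_minimal()
}
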
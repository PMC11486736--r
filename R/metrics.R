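#' Regression evaluation metrics, globally and per group
#'
#' Computes the mean absolute error \eqn{\mathrm{MAE} = \frac1n\sum|\hat y_i -
#' y_i|}, the root mean square error \eqn{\mathrm{RMSE} = \sqrt{\frac1n\sum
#' (\hat y_i - y_i)^2}} and the coefficient of determination
#' \eqn{R^2 = 1 - \sum(\hat y_i - y_i)^2 / \sum(\bar y - y_i)^2}. When
#' `groups` is supplied, one additional row per group is computed on that
#' group's subset (groups too small or too constant for \eqn{R^2} get `NA`
#' there). Yield metrics in this package are always computed in original
#' units, after inverting the z-score transform.
#'
#' @param pred,true Equal-length numeric vectors.
#' @param groups Optional per-observation group labels (planting locations).
#' @return A tibble with columns `group` (`"(all)"` first), `n`, `mae`,
#'   `rmse`, `r2`.
#' @examples
#' compute_metrics(c(1, 1), c(0, 2))  # mae 1, rmse 1, r2 0
#' @export
compute_metrics <- function(pred, true, groups = NULL) {
  if (length(pred) != length(true)) stop("pred and true must have equal length", call. = FALSE)
  if (length(pred) < 1L) stop("empty input", call. = FALSE)

  global <- metrics_one(pred, true, require_r2 = TRUE)
  out <- tibble::tibble(group = "(all)", n = length(pred),
                        mae = global$mae, rmse = global$rmse, r2 = global$r2)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(pred))
    per <- tibble::tibble(group = as.character(groups), pred = pred, true = true) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        n = dplyr::n(),
        mae = mean(abs(.data$pred - .data$true)),
        rmse = sqrt(mean((.data$pred - .data$true)^2)),
        r2 = {
          tv <- .data$true
          ss_tot <- sum((mean(tv) - tv)^2)
          if (dplyr::n() >= 2 && ss_tot > 0) {
            1 - sum((.data$pred - tv)^2) / ss_tot
          } else NA_real_
        },
        .groups = "drop"
      )
    out <- dplyr::bind_rows(out, per)
  }
  class(out) <- c("bgy_metrics", class(out))
  out
}

metrics_one <- function(pred, true, require_r2 = FALSE) {
  mae <- mean(abs(pred - true))
  rmse <- sqrt(mean((pred - true)^2))
  ss_tot <- sum((mean(true) - true)^2)
  r2 <- if (length(true) >= 2 && ss_tot > 0) {
    1 - sum((pred - true)^2) / ss_tot
  } else {
    if (require_r2) stop("R^2 undefined: need >= 2 observations with ",
                         "non-constant true values", call. = FALSE)
    NA_real_
  }
  list(mae = mae, rmse = rmse, r2 = r2)
}

#' Write a metrics report as JSON
#'
#' Emits `{global: {...}, per_group: {...}, n, config_hash}` for downstream
#' consumption.
#'
#' @param metrics A tibble from [compute_metrics()].
#' @param path Output path.
#' @param config Optional list whose serialized form is hashed into
#'   `config_hash` to tie a report to the run configuration.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path, config = NULL) {
  glob <- metrics[metrics$group == "(all)", ]
  per <- metrics[metrics$group != "(all)", ]
  report <- list(
    global = list(MAE = glob$mae, RMSE = glob$rmse, R2 = glob$r2),
    per_group = if (nrow(per) > 0) {
      stats::setNames(
        purrr::map(seq_len(nrow(per)), function(i) {
          list(MAE = per$mae[i], RMSE = per$rmse[i], R2 = per$r2[i], n = per$n[i])
        }),
        per$group
      )
    } else NULL,
    n = glob$n,
    config_hash = config_digest(config)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# small stable hash of a config list (no external digest dependency)
config_digest <- function(config) {
  if (is.null(config)) return(NA_character_)
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
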
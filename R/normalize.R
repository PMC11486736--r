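#' Fit per-column z-score parameters
#'
#' Computes the per-column mean and population (divide-by-N) standard
#' deviation over *observed* cells of the *fit rows* only, so that parameters
#' estimated on training rows can be frozen and applied to held-out rows
#' without leakage. All columns — encoded categorical traits and the yield
#' included — are standardized by default, matching how the network consumes
#' the table; metrics are reported after the inverse transform.
#'
#' @param x An encoded [feature_table][as_feature_table] (no text columns).
#' @param fit_rows Integer vector of rows used to estimate the parameters
#'   (default: all rows).
#' @param columns Character vector of columns to standardize (default: all
#'   value columns).
#' @return A `norm_params` tibble with columns `column`, `mu`, `sigma`,
#'   `normalized`.
#' @examples
#' ft <- as_feature_table(tibble::tibble(a = c(1, 2, 3), yield = c(2, 4, 6)))
#' fit_normalizer(ft)
#' @export
fit_normalizer <- function(x, fit_rows = NULL, columns = NULL) {
  vals <- ft_values(x)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(vals))
  stopifnot(all(fit_rows >= 1), all(fit_rows <= nrow(vals)))
  if (is.null(columns)) columns <- colnames(vals)

  params <- purrr::map_dfr(colnames(vals), function(nm) {
    do_norm <- nm %in% columns
    v <- vals[fit_rows, nm]
    v <- v[!is.na(v)]
    if (do_norm) {
      if (length(v) < 2L) {
        stop("column '", nm, "' has fewer than 2 observed values among fit rows",
             call. = FALSE)
      }
      mu <- mean(v)
      sigma <- sqrt(mean((v - mu)^2))  # population sd
      if (sigma <= 0) {
        stop("column '", nm, "' is constant on fit rows (sigma = 0); ",
             "cannot z-score", call. = FALSE)
      }
    } else {
      mu <- 0; sigma <- 1
    }
    tibble::tibble(column = nm, mu = mu, sigma = sigma, normalized = do_norm)
  })
  class(params) <- c("norm_params", class(params))
  params
}

#' Apply or invert fitted z-score parameters
#'
#' `apply_normalizer()` maps every normalized column through
#' \eqn{t' = (t - \mu)/\sigma} using the frozen parameters (never
#' re-estimating them); `invert_normalizer()` maps back. Missing cells stay
#' missing; the two are exact inverses.
#'
#' @param x An encoded `feature_table`.
#' @param params A `norm_params` object from [fit_normalizer()].
#' @return A `feature_table` on the transformed scale.
#' @export
apply_normalizer <- function(x, params) {
  transform_with_params(x, params, invert = FALSE)
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(x, params) {
  transform_with_params(x, params, invert = TRUE)
}

transform_with_params <- function(x, params, invert) {
  sch <- ft_schema(x)
  missing_cols <- setdiff(sch$name, params$column)
  if (length(missing_cols) > 0L) {
    stop("norm params missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(x)
  for (i in seq_len(nrow(params))) {
    nm <- params$column[i]
    if (!params$normalized[i] || !nm %in% names(data)) next
    if (invert) {
      data[[nm]] <- data[[nm]] * params$sigma[i] + params$mu[i]
    } else {
      data[[nm]] <- (data[[nm]] - params$mu[i]) / params$sigma[i]
    }
  }
  new_feature_table(data, sch, attr(x, "yield_col"), attr(x, "group_col"))
}

#' One-shot z-score normalization
#'
#' Convenience wrapper: fits on `fit_rows` and applies to the whole table.
#'
#' @inheritParams fit_normalizer
#' @return A list with elements `table` (normalized `feature_table`) and
#'   `params` (`norm_params`).
#' @export
zscore_normalize <- function(x, fit_rows = NULL, columns = NULL) {
  params <- fit_normalizer(x, fit_rows = fit_rows, columns = columns)
  list(table = apply_normalizer(x, params), params = params)
}

#' Persist normalization parameters
#'
#' Written as plain CSV so fitted parameters can be reused at inference.
#'
#' @param params A `norm_params` object.
#' @param path Output path.
#' @return `path` invisibly; `read_norm_params()` returns the `norm_params`.
#' @export
write_norm_params <- function(params, path) {
  readr::write_csv(tibble::as_tibble(params), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_norm_params
#' @export
read_norm_params <- function(path) {
  params <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("column", "mu", "sigma", "normalized") %in% names(params)))
  class(params) <- c("norm_params", class(params))
  params
}
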
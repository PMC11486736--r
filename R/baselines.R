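#' Simple imputation baselines
#'
#' Column-wise mean and median fills, and a k-nearest-neighbour fill: for a
#' row with a missing cell, the k nearest rows (Euclidean distance over the
#' columns observed in both rows, normalized by the number of shared
#' columns) that observe the target column donate their mean value. Rows
#' sharing no observed column with the target row, or columns with no donor,
#' fall back to the column mean. Categorical cells are rounded to the
#' nearest valid label afterwards.
#'
#' @param x An encoded [feature_table][as_feature_table] (yield is never
#'   imputed by these baselines).
#' @param method `"mean"`, `"median"` or `"knn"`.
#' @param k Number of neighbours for `method = "knn"` (default 5).
#' @return A `feature_table` with feature cells filled.
#' @examples
#' ft <- as_feature_table(tibble::tibble(a = c(1, 2, 3, NA), yield = 1:4))
#' baseline_impute(ft, "mean")$a[4]  # 2
#' @export
baseline_impute <- function(x, method = c("mean", "median", "knn"), k = 5) {
  method <- match.arg(method)
  sch <- ft_schema(x)
  yc <- attr(x, "yield_col")
  feat <- ft_feature_names(x)
  vals <- ft_values(x)[, feat, drop = FALSE]

  all_missing <- colSums(!is.na(vals)) == 0
  if (any(all_missing)) {
    stop("column(s) with no observed value: ",
         paste(feat[all_missing], collapse = ", "), call. = FALSE)
  }

  filled <- switch(method,
    mean = fill_columnwise(vals, function(v) mean(v, na.rm = TRUE)),
    median = fill_columnwise(vals, function(v) stats::median(v, na.rm = TRUE)),
    knn = fill_knn(vals, k = k)
  )

  data <- tibble::as_tibble(x)
  for (nm in feat) {
    i <- match(nm, sch$name)
    col <- filled[, nm]
    if (sch$kind[i] == "categorical") {
      n_lab <- length(sch$label_map[[i]])
      if (n_lab == 0) n_lab <- max(col, na.rm = TRUE)
      col <- pmin(pmax(round(col), 1), n_lab)
    }
    miss <- is.na(data[[nm]])
    data[[nm]][miss] <- col[miss]
  }
  new_feature_table(data, sch, yc, attr(x, "group_col"))
}

fill_columnwise <- function(vals, fun) {
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    v[is.na(v)] <- fun(v)
    vals[, j] <- v
  }
  vals
}

fill_knn <- function(vals, k) {
  n <- nrow(vals)
  obs <- !is.na(vals)
  col_means <- colMeans(vals, na.rm = TRUE)
  # pairwise distances over mutually observed columns (mean squared diff)
  z <- vals; z[!obs] <- 0
  o <- obs * 1
  # sum over shared cols of (a-b)^2 = a^2.o + o.b^2 - 2ab restricted to both observed
  sq <- (z^2) %*% t(o)
  cross <- z %*% t(z)
  shared <- o %*% t(o)
  d2 <- sq + t(sq) - 2 * cross
  d2 <- d2 / pmax(shared, 1)     # per-column normalization
  d2[shared == 0] <- Inf          # no overlap: unusable neighbour
  diag(d2) <- Inf

  out <- vals
  for (i in seq_len(n)) {
    miss_j <- which(!obs[i, ])
    if (length(miss_j) == 0L) next
    ord <- order(d2[i, ])
    for (j in miss_j) {
      donors <- ord[obs[ord, j] & is.finite(d2[i, ord])]
      donors <- donors[seq_len(min(k, length(donors)))]
      out[i, j] <- if (length(donors) > 0) mean(vals[donors, j]) else col_means[j]
    }
  }
  out
}
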
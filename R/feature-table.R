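#' Construct a feature table
#'
#' A feature table is the package's tabular container for multi-environment
#' trial data: one row per planting observation, one column per feature
#' (meteorological aggregates and growth traits, continuous or categorical),
#' one yield column (always kept last), and optionally a grouping column
#' identifying the planting location. Missing cells are plain `NA`; the
#' missingness mask is always derived from the data, never stored as a magic
#' number.
#'
#' @param data A data frame or tibble. Feature columns must be numeric or
#'   character/factor (character and factor columns are treated as
#'   categorical traits and can be label-encoded with
#'   [encode_categoricals()]).
#' @param yield_col Name of the yield column. Defaults to `"yield"` when
#'   present, otherwise the last non-group column.
#' @param group_col Optional name of the grouping (planting location) column.
#'   It is carried along but never enters the value matrix.
#' @param categorical Character vector of additional column names to treat as
#'   categorical even though they are already numeric (e.g. pre-encoded
#'   labels).
#' @param label_maps Optional named list of character vectors giving the
#'   level-to-label mapping for categorical columns (level i of the vector
#'   encodes as integer i). Usually produced by [encode_categoricals()].
#'
#' @return A `feature_table`: a tibble with attributes `ft_schema` (per-column
#'   name/kind/label map), `yield_col` and `group_col`.
#' @examples
#' tbl <- tibble::tibble(
#'   site  = c("a", "a", "b"),
#'   tmax  = c(29.1, 31.2, 27.8),
#'   color = c("white", "red", NA),
#'   yield = c(612, 640, 598)
#' )
#' ft <- as_feature_table(tbl, group_col = "site")
#' ft_schema(ft)
#' @export
as_feature_table <- function(data, yield_col = NULL, group_col = NULL,
                             categorical = NULL, label_maps = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (nrow(data) < 1L) stop("feature table must have at least one row", call. = FALSE)

  if (!is.null(group_col)) {
    if (!group_col %in% names(data)) {
      stop("group column '", group_col, "' not found", call. = FALSE)
    }
  }
  value_cols <- setdiff(names(data), group_col)
  if (is.null(yield_col)) {
    yield_col <- if ("yield" %in% value_cols) "yield" else value_cols[length(value_cols)]
  }
  if (!yield_col %in% value_cols) {
    stop("yield column '", yield_col, "' not found", call. = FALSE)
  }
  feature_cols <- setdiff(value_cols, yield_col)
  if (length(feature_cols) < 1L) {
    stop("feature table must have at least one feature column besides yield",
         call. = FALSE)
  }

  ok_type <- vapply(data[value_cols], function(col) {
    is.numeric(col) || is.character(col) || is.factor(col)
  }, logical(1))
  if (!all(ok_type)) {
    stop("columns must be numeric, character or factor: ",
         paste(value_cols[!ok_type], collapse = ", "), call. = FALSE)
  }
  data <- dplyr::mutate(data, dplyr::across(dplyr::where(is.factor), as.character))

  kind <- vapply(value_cols, function(nm) {
    if (is.character(data[[nm]]) || nm %in% categorical) "categorical" else "continuous"
  }, character(1))
  if (kind[match(yield_col, value_cols)] == "categorical") {
    stop("yield column must be continuous", call. = FALSE)
  }

  schema <- tibble::tibble(
    name = value_cols,
    kind = unname(kind),
    label_map = lapply(value_cols, function(nm) {
      if (!is.null(label_maps) && nm %in% names(label_maps)) label_maps[[nm]] else NULL
    })
  )
  # canonical column order: group first (if any), features, yield last
  data <- data[, c(group_col, feature_cols, yield_col), drop = FALSE]
  schema <- schema[match(c(feature_cols, yield_col), schema$name), ]

  new_feature_table(data, schema, yield_col, group_col)
}

new_feature_table <- function(data, schema, yield_col, group_col) {
  structure(
    data,
    ft_schema = schema,
    yield_col = yield_col,
    group_col = group_col,
    class = c("feature_table", class(tibble::tibble()))
  )
}

#' @export
print.feature_table <- function(x, ...) {
  sch <- ft_schema(x)
  n_cat <- sum(sch$kind == "categorical")
  cat(sprintf(
    "# A feature_table: %d observations x %d features (+ yield '%s'%s), %d categorical\n",
    nrow(x), nrow(sch) - 1L, attr(x, "yield_col"),
    if (is.null(attr(x, "group_col"))) "" else paste0(", groups '", attr(x, "group_col"), "'"),
    n_cat
  ))
  NextMethod()
}

#' Feature-table accessors
#'
#' `ft_schema()` returns the per-column schema (name, kind, label map);
#' `ft_values()` the numeric observation-by-column matrix (features then yield;
#' categorical columns must be label-encoded first); `ft_mask()` the logical
#' observed-mask of the same shape (`TRUE` = observed); `ft_groups()` the
#' per-observation group labels (or a single `"all"` group when no group
#' column is set); `ft_feature_names()` the feature column names without the
#' yield column.
#'
#' @param x A `feature_table`.
#' @return See each description above.
#' @export
ft_schema <- function(x) {
  sch <- attr(x, "ft_schema")
  if (is.null(sch)) stop("not a feature_table; see as_feature_table()", call. = FALSE)
  sch
}

#' @rdname ft_schema
#' @export
ft_values <- function(x) {
  sch <- ft_schema(x)
  cols <- x[, sch$name, drop = FALSE]
  chr <- vapply(cols, is.character, logical(1))
  if (any(chr)) {
    stop("categorical columns still hold text labels (",
         paste(sch$name[chr], collapse = ", "),
         "); run encode_categoricals() first", call. = FALSE)
  }
  m <- as.matrix(cols)
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, sch$name)
  m
}

#' @rdname ft_schema
#' @export
ft_mask <- function(x) {
  sch <- ft_schema(x)
  !is.na(as.matrix(x[, sch$name, drop = FALSE]))
}

#' @rdname ft_schema
#' @export
ft_groups <- function(x) {
  gc <- attr(x, "group_col")
  if (is.null(gc)) rep("all", nrow(x)) else as.character(x[[gc]])
}

#' @rdname ft_schema
#' @export
ft_feature_names <- function(x) {
  sch <- ft_schema(x)
  sch$name[sch$name != attr(x, "yield_col")]
}

# rebuild a feature_table after mutating the underlying data, keeping schema
ft_replace_data <- function(x, data) {
  new_feature_table(tibble::as_tibble(data), ft_schema(x),
                    attr(x, "yield_col"), attr(x, "group_col"))
}

#' Read a feature table from a delimited file
#'
#' Reads a CSV/TSV with a header row into a [feature_table][as_feature_table].
#' The missingness mask reflects the configured NA tokens exactly; column
#' order is preserved except that the yield column is moved last.
#'
#' @inheritParams as_feature_table
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter (default comma).
#' @param na Character vector of tokens read as missing (default `"NA"` and
#'   the empty string).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, delim = ",", na = c("NA", ""),
                               yield_col = NULL, group_col = NULL,
                               categorical = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- readr::read_delim(path, delim = delim, na = na,
                            show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(data)
  if (nrow(probs) > 0L) {
    stop("malformed table (", nrow(probs), " parsing problem(s), first at row ",
         probs$row[1], "): ", probs$expected[1], call. = FALSE)
  }
  if (nrow(data) == 0L) stop("table has a header but no rows: ", path, call. = FALSE)
  as_feature_table(data, yield_col = yield_col, group_col = group_col,
                   categorical = categorical)
}

#' Write a feature table to a delimited file
#'
#' Inverse of [read_feature_table()]: `read_feature_table(write_feature_table(x))`
#' reproduces values, mask and column order.
#'
#' @param x A `feature_table`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param na Token written for missing cells.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, delim = ",", na = "NA") {
  readr::write_delim(tibble::as_tibble(x), path, delim = delim, na = na,
                     progress = FALSE)
  invisible(path)
}
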
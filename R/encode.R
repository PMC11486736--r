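#' Label-encode categorical trait columns
#'
#' Text-valued traits (variety, grain color, axis color, ...) are converted to
#' positive integer labels so they can enter the numeric value matrix: the
#' first distinct observed category of a column becomes 1, the second 2, and
#' so on, in order of first appearance. An explicit `label_maps` entry
#' overrides this ordering (level i of the supplied character vector encodes
#' as integer i), which is how a mapping frozen on training data is re-applied
#' at inference. Missing cells stay missing.
#'
#' @param x A [feature_table][as_feature_table].
#' @param label_maps Optional named list of character vectors fixing the
#'   category-to-label mapping for some or all categorical columns. With a
#'   frozen map, a category unseen in the map is an error.
#' @return A `feature_table` whose categorical columns hold integer labels and
#'   whose schema records the label map of every categorical column.
#' @seealso [decode_categoricals()] for the inverse.
#' @examples
#' tbl <- tibble::tibble(axis = c("white", "red", "pink", "purple"),
#'                       yield = c(1, 2, 3, 4))
#' encode_categoricals(as_feature_table(tbl))$axis  # 1 2 3 4
#' @export
encode_categoricals <- function(x, label_maps = NULL) {
  sch <- ft_schema(x)
  data <- tibble::as_tibble(x)
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    if (sch$kind[i] != "categorical") next
    col <- data[[nm]]
    map <- if (!is.null(label_maps) && nm %in% names(label_maps)) {
      label_maps[[nm]]
    } else if (!is.null(sch$label_map[[i]])) {
      sch$label_map[[i]]
    } else NULL

    if (is.character(col)) {
      if (is.null(map)) {
        map <- unique(col[!is.na(col)])  # first-appearance order
      } else {
        unseen <- setdiff(col[!is.na(col)], map)
        if (length(unseen) > 0L) {
          stop("column '", nm, "': categories not in frozen label map: ",
               paste(unseen, collapse = ", "), call. = FALSE)
        }
      }
      data[[nm]] <- as.integer(match(col, map))
    } else {
      # already numeric labels; validate and keep, recording a map if absent
      obs <- col[!is.na(col)]
      if (length(obs) > 0L && (any(obs < 1) || any(obs != round(obs)))) {
        stop("column '", nm, "' is categorical but holds non positive-integer ",
             "values", call. = FALSE)
      }
      if (is.null(map)) map <- as.character(seq_len(max(c(obs, 1))))
    }
    sch$label_map[[i]] <- map
  }
  new_feature_table(data, sch, attr(x, "yield_col"), attr(x, "group_col"))
}

#' Decode integer labels back to category text
#'
#' Inverse of [encode_categoricals()] for columns whose label map stores the
#' original text categories. Labels outside the map are an error.
#'
#' @param x An encoded `feature_table`.
#' @return A `feature_table` with text categories restored.
#' @export
decode_categoricals <- function(x) {
  sch <- ft_schema(x)
  data <- tibble::as_tibble(x)
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    map <- sch$label_map[[i]]
    if (sch$kind[i] != "categorical" || is.null(map)) next
    col <- data[[nm]]
    if (!is.numeric(col)) next
    bad <- !is.na(col) & (col < 1 | col > length(map) | col != round(col))
    if (any(bad)) {
      stop("column '", nm, "': labels outside the label map range", call. = FALSE)
    }
    data[[nm]] <- map[as.integer(col)]
  }
  new_feature_table(data, sch, attr(x, "yield_col"), attr(x, "group_col"))
}

#' Extract the label maps of an encoded table
#'
#' @param x A `feature_table`.
#' @return Named list of character vectors, one per categorical column with a
#'   recorded map.
#' @export
ft_label_maps <- function(x) {
  sch <- ft_schema(x)
  maps <- sch$label_map
  names(maps) <- sch$name
  maps[!vapply(maps, is.null, logical(1))]
}
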
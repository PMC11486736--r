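#' Aggregate daily weather series to per-sample mean/variance features
#'
#' Daily meteorological readings (10 dimensions: max/mean/min temperature,
#' temperature range, ground pressure, relative humidity, precipitation,
#' mean/max wind speed, sunshine hours, ...) recorded over each sample's
#' growth window are collapsed to one row per sample holding the per-dimension
#' mean and population variance — so 10 daily dimensions become 20 static
#' features. The mean captures the average level over the growth cycle, the
#' variance its day-to-day variation. Population (divide-by-N) variance is
#' used, so a one-day window yields variance 0 rather than NA.
#'
#' @param daily A long-format data frame: one row per sample per day, with an
#'   id column, a date column and one numeric column per meteorological
#'   dimension.
#' @param id_col Name of the sample id column (default `"sample_id"`).
#' @param date_col Name of the date column (default `"date"`).
#' @param windows Optional data frame (`sample_id`, `start`, `end`) restricting
#'   each sample to its growth window; by default every supplied day is used.
#' @return A tibble with one row per sample: the id column, then
#'   `<dim>_mean` and `<dim>_var` columns.
#' @examples
#' daily <- tibble::tibble(
#'   sample_id = rep("s1", 3),
#'   date = as.Date("2021-06-01") + 0:2,
#'   tmax = c(28, 30, 32), rain = c(0, 4, 2)
#' )
#' aggregate_daily_weather(daily)
#' @export
aggregate_daily_weather <- function(daily, id_col = "sample_id",
                                    date_col = "date", windows = NULL) {
  stopifnot(is.data.frame(daily))
  if (!id_col %in% names(daily)) stop("id column '", id_col, "' not found", call. = FALSE)
  if (!date_col %in% names(daily)) stop("date column '", date_col, "' not found", call. = FALSE)
  daily <- tibble::as_tibble(daily)

  if (!is.null(windows)) {
    stopifnot(all(c(id_col, "start", "end") %in% names(windows)))
    daily <- dplyr::inner_join(daily, windows, by = id_col)
    daily <- dplyr::filter(daily, .data[[date_col]] >= .data$start,
                           .data[[date_col]] <= .data$end)
    daily <- dplyr::select(daily, -dplyr::all_of(c("start", "end")))
    if (nrow(daily) == 0L) {
      stop("empty growth window: no daily rows fall inside any window", call. = FALSE)
    }
  }

  dims <- setdiff(names(daily), c(id_col, date_col))
  if (length(dims) == 0L) stop("no meteorological columns found", call. = FALSE)
  num <- vapply(daily[dims], is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric meteorological columns: ", paste(dims[!num], collapse = ", "),
         call. = FALSE)
  }

  pop_var <- function(v) mean((v - mean(v))^2)
  out <- daily |>
    dplyr::group_by(.data[[id_col]]) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(dims),
                    list(mean = mean, var = pop_var),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    )
  # order columns as [means..., vars...] to mirror the 10 -> 20 layout
  out[, c(id_col, paste0(dims, "_mean"), paste0(dims, "_var"))]
}
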
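# small table fixtures built in code

toy_table <- function() {
  as_feature_table(tibble::tibble(
    tmax = c(29.1, 31.2, 27.8, 30.0),
    rain = c(12.0, NA, 8.5, 10.1),
    axis_color = c("white", "red", "pink", "purple"),
    yield = c(612, 640, 598, 625)
  ), group_col = NULL, yield_col = "yield")
}

# table with a prescribed per-row missing-feature count
missingness_table <- function(counts, m = 4) {
  n <- length(counts)
  vals <- matrix(seq_len(n * m) + 0.5, n, m)
  for (i in seq_len(n)) {
    if (counts[i] > 0) vals[i, seq_len(counts[i])] <- NA
  }
  df <- tibble::as_tibble(as.data.frame(vals))
  names(df) <- paste0("f", seq_len(m))
  df$yield <- seq_len(n) * 10
  as_feature_table(df)
}

expect_tables_equal <- function(a, b, tol = 1e-12) {
  expect_equal(names(a), names(b))
  expect_equal(ft_schema(a)$kind, ft_schema(b)$kind)
  va <- as.data.frame(a); vb <- as.data.frame(b)
  for (nm in names(va)) {
    if (is.numeric(va[[nm]])) {
      expect_equal(va[[nm]], vb[[nm]], tolerance = tol)
    } else {
      expect_identical(va[[nm]], vb[[nm]])
    }
  }
}
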
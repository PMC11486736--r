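test_that("a 2x2 table plus yield yields 2 obs nodes, 3 feat nodes, 6 edges", {
  ft <- as_feature_table(tibble::tibble(a = c(1, 2), b = c(3, 4),
                                        yield = c(5, 6)))
  g <- build_bipartite_graph(ft)
  expect_equal(g$n, 2L)
  expect_equal(g$m1, 3L)
  expect_equal(length(g$weights), 6L)  # complete bipartite: n x (m+1)
})

test_that("missing cells become zero-weight, unsupervised edges", {
  ft <- as_feature_table(tibble::tibble(a = c(1, 2), b = c(NA, 4),
                                        yield = c(5, 6)))
  g <- build_bipartite_graph(ft)
  expect_equal(g$weights[1, 2], 0)
  expect_false(g$supervised[1, 2])
  expect_true(g$supervised[2, 2])
})

test_that("hiding a row's yield zeroes the edge and drops supervision", {
  ft <- as_feature_table(tibble::tibble(a = c(1, 2), yield = c(5, 6)))
  g <- build_bipartite_graph(ft, hide_yield_for = 1L)
  expect_equal(g$weights[1, 2], 0)
  expect_false(g$supervised[1, 2])
  expect_equal(g$obs_init[1, ], c(1, 0))
})

test_that("node initializations follow the one-hot / observed-mask scheme", {
  ft <- as_feature_table(tibble::tibble(a = c(1, 2), b = c(NA, 4),
                                        yield = c(5, 6)))
  g <- build_bipartite_graph(ft)
  expect_equal(g$feat_init[2, ], c(0, 1, 0))   # F_2 one-hot
  expect_equal(g$obs_init[1, ], c(1, 0, 1))    # dimension 2 missing
  expect_equal(g$obs_init[2, ], c(1, 1, 1))    # fully observed row
})

test_that("bipartite invariants hold over random tables", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(1:8, 1); m1 <- sample(2:6, 1)
    g <- random_graph(n, m1, missing_frac = runif(1, 0, 0.4))
    expect_equal(dim(g$weights), c(n, m1))
    expect_equal(length(g$weights), n * m1)
    expect_true(all(g$weights[!g$supervised] == 0))
    expect_true(all(g$obs_init %in% c(0, 1)))
    expect_equal(g$feat_init, diag(m1))
  }
})

test_that("supervised edges reconstruct exactly the observed non-hidden cells", {
  set.seed(7)
  df <- tibble::as_tibble(as.data.frame(matrix(rnorm(40), 8)))
  names(df) <- c(paste0("f", 1:4), "yield")
  df$f2[c(1, 3)] <- NA
  ft <- as_feature_table(df)
  g <- build_bipartite_graph(ft, hide_yield_for = c(2, 5))
  rec <- graph_to_matrix(g)
  vals <- ft_values(ft)
  vals[c(1, 3), "f2"] <- NA
  vals[c(2, 5), "yield"] <- NA
  expect_equal(rec, vals)
})

test_that("row permutation permutes observation nodes and edges consistently", {
  set.seed(5)
  df <- tibble::as_tibble(as.data.frame(matrix(rnorm(30), 6)))
  names(df) <- c(paste0("f", 1:4), "yield")
  df$f3[2] <- NA
  perm <- sample(6)
  g1 <- build_bipartite_graph(as_feature_table(df))
  g2 <- build_bipartite_graph(as_feature_table(df[perm, ]))
  expect_equal(g2$weights, g1$weights[perm, ])
  expect_equal(g2$obs_init, g1$obs_init[perm, ])
  expect_equal(g2$supervised, g1$supervised[perm, ])
})

test_that("edge-list serialization round-trips the graph", {
  set.seed(11)
  g <- random_graph(5, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph_edges(g, path)
  g2 <- read_graph_edges(path)
  expect_equal(g2$weights, unname(g$weights))
  expect_equal(matrix(as.logical(g2$supervised), g$n), unname(g$supervised))
  expect_equal(g2$obs_init, unname(g$obs_init))
  expect_equal(g2$feat_init, g$feat_init)
})

test_that("degenerate tables are rejected", {
  ft <- as_feature_table(tibble::tibble(a = 1, yield = 2))
  expect_error(build_bipartite_graph(ft, hide_yield_for = 5L), "out of range")
})
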
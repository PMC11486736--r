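#' Build the bipartite graph of a feature table
#'
#' Converts an encoded, standardized feature table into the graph the network
#' operates on: `n` observation nodes (one per row), `m + 1` feature nodes
#' (one per feature column plus the yield), and the *complete* edge set of
#' `n * (m + 1)` weighted edges. Edge `(i, j)` carries the standardized cell
#' value when the cell is observed and 0 when it is missing — missing cells
#' are present zero-weight edges, not absent edges. Yield edges of rows listed
#' in `hide_yield_for` (the evaluation rows) are forcibly zeroed and excluded
#' from supervision before any message passing, so their labels can never
#' leak into training.
#'
#' Node initializations follow the one-hot/mask scheme: feature node `F_j`
#' starts as the `(m+1)`-dimensional unit vector with 1 in dimension `j`;
#' observation node `N_i` starts as its observed-cell indicator (1 where the
#' cell is observed and not hidden, 0 where missing), all ones for a complete
#' row.
#'
#' @param x An encoded [feature_table][as_feature_table]; standardize it first
#'   (see [zscore_normalize()]) so edge weights are comparable across columns.
#' @param hide_yield_for Integer vector of rows whose yield must be invisible
#'   to the network (test rows).
#' @param include_yield If `FALSE`, the yield column is dropped entirely and
#'   the graph has only the `m` trait/weather feature nodes — the trait-only
#'   variant used for pure imputation benchmarking.
#' @return A `bipartite_graph` object: fields `n`, `m1` (number of feature
#'   nodes), `weights` (`n x m1` edge-weight matrix), `supervised` (`n x m1`
#'   logical: observed and not hidden), `obs_init` (`n x m1`), `feat_init`
#'   (`m1 x m1` identity), `feat_names`, `hide_yield_for`, `has_yield`.
#' @examples
#' ft <- as_feature_table(tibble::tibble(a = c(1, NA), b = c(0.5, -0.5),
#'                                       yield = c(1, 2)))
#' g <- build_bipartite_graph(ft)
#' g$n * g$m1  # 6 edges
#' @export
build_bipartite_graph <- function(x, hide_yield_for = integer(),
                                  include_yield = TRUE) {
  vals <- ft_values(x)
  mask <- ft_mask(x)
  if (!include_yield) {
    keep <- colnames(vals) != attr(x, "yield_col")
    vals <- vals[, keep, drop = FALSE]
    mask <- mask[, keep, drop = FALSE]
    hide_yield_for <- integer()
  }
  n <- nrow(vals); m1 <- ncol(vals)
  if (n < 1L || m1 < 1L) stop("cannot build graph from an empty table", call. = FALSE)
  hide_yield_for <- as.integer(hide_yield_for)
  if (length(hide_yield_for) > 0L &&
      (any(hide_yield_for < 1L) || any(hide_yield_for > n))) {
    stop("hide_yield_for rows out of range", call. = FALSE)
  }

  observed <- mask
  if (include_yield && length(hide_yield_for) > 0L) {
    observed[hide_yield_for, m1] <- FALSE  # hidden = treated as missing
  }
  feat_names <- colnames(vals)
  weights <- unname(vals)
  observed <- unname(observed)
  weights[!observed] <- 0

  g <- structure(list(
    n = n, m1 = m1,
    weights = weights,
    supervised = observed,
    obs_init = NULL, feat_init = NULL,
    feat_names = feat_names,
    hide_yield_for = sort(hide_yield_for),
    has_yield = include_yield
  ), class = "bipartite_graph")
  init_node_features(g)
}

#' Initialize node feature vectors
#'
#' (Re)computes the one-hot feature-node and observed-mask observation-node
#' initial vectors of a graph; called by [build_bipartite_graph()] and
#' exposed for direct use.
#'
#' @param graph A `bipartite_graph`.
#' @return The graph with `obs_init` and `feat_init` filled.
#' @export
init_node_features <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  graph$feat_init <- diag(graph$m1)
  graph$obs_init <- matrix(as.numeric(graph$supervised), graph$n, graph$m1)
  graph
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(
    "# bipartite_graph: %d obs nodes x %d feature nodes, %d edges (%d supervised)%s\n",
    x$n, x$m1, x$n * x$m1, sum(x$supervised),
    if (length(x$hide_yield_for)) sprintf(", %d yields hidden", length(x$hide_yield_for)) else ""
  ))
  invisible(x)
}

#' Serialize a bipartite graph to plain text
#'
#' Writes the edge list (`obs_id`, `feat_id`, `weight`, `supervised`) as TSV
#' plus a node-init sidecar (`<path>.nodes.tsv`); `read_graph_edges()`
#' restores an identical graph.
#'
#' @param graph A `bipartite_graph`.
#' @param path Output TSV path for the edge list.
#' @return `path` invisibly; `read_graph_edges()` returns the graph.
#' @export
write_graph_edges <- function(graph, path) {
  edges <- tibble::tibble(
    obs_id = rep(seq_len(graph$n), graph$m1),
    feat_id = rep(graph$feat_names, each = graph$n),
    weight = as.vector(graph$weights),
    supervised = as.vector(graph$supervised)
  )
  readr::write_tsv(edges, path, progress = FALSE)
  nodes <- tibble::tibble(
    node = c(paste0("N", seq_len(graph$n)), paste0("F", seq_len(graph$m1))),
    init = c(apply(graph$obs_init, 1, paste, collapse = ","),
             apply(graph$feat_init, 1, paste, collapse = ","))
  )
  nodes$meta <- c(rep(if (length(graph$hide_yield_for)) "" else "", graph$n), graph$feat_names)
  nodes$meta[graph$hide_yield_for] <- "yield_hidden"
  readr::write_tsv(nodes, paste0(path, ".nodes.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_graph_edges
#' @export
read_graph_edges <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"), show_col_types = FALSE,
                           progress = FALSE)
  feat_names <- unique(edges$feat_id)
  n <- max(edges$obs_id); m1 <- length(feat_names)
  stopifnot(nrow(edges) == n * m1)
  ord <- order(match(edges$feat_id, feat_names), edges$obs_id)
  edges <- edges[ord, ]
  parse_init <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  obs_init <- do.call(rbind, lapply(nodes$init[seq_len(n)], parse_init))
  feat_init <- do.call(rbind, lapply(nodes$init[n + seq_len(m1)], parse_init))
  hidden <- which(!is.na(nodes$meta[seq_len(n)]) & nodes$meta[seq_len(n)] == "yield_hidden")
  structure(list(
    n = n, m1 = m1,
    weights = matrix(edges$weight, n, m1),
    supervised = matrix(edges$supervised, n, m1),
    obs_init = obs_init, feat_init = feat_init,
    feat_names = feat_names,
    hide_yield_for = as.integer(hidden),
    has_yield = TRUE
  ), class = "bipartite_graph")
}

#' Recover the observed table from a graph
#'
#' Returns the `n x m1` matrix of supervised edge weights with unsupervised
#' cells `NA` — reconstructing exactly the observed, non-hidden cells of the
#' table the graph was built from (on the standardized scale).
#'
#' @param graph A `bipartite_graph`.
#' @return A numeric matrix with `NA` at unsupervised cells.
#' @export
graph_to_matrix <- function(graph) {
  m <- graph$weights
  m[!graph$supervised] <- NA
  colnames(m) <- graph$feat_names
  m
}
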
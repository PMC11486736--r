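#' Initialize bipartite network parameters
#'
#' Allocates the weights of the stacked graph update layers and the two-layer
#' prediction head. Each update layer holds two affine transforms: `L_A`,
#' applied to the concatenation of a neighbor's embedding with the connecting
#' edge embedding (one "message" per directed edge), and `L_B`, applied to
#' the concatenation of the summed messages with the node's own embedding.
#' Both node types share the same transforms — the update rule is identical
#' for observation and feature nodes. Edge embeddings are never projected:
#' after each layer the edge embedding is the concatenation of its two
#' endpoint embeddings with its previous value, so its dimension grows from 1
#' to `2*hidden*l + 1` after layer `l`; with the default three layers the
#' growth stays bounded. Weights are Glorot-uniform initialized.
#'
#' @param m1 Number of feature nodes (features + yield) — the input embedding
#'   dimension of every node.
#' @param n_layers Number of graph update layers (default 3).
#' @param hidden Hidden width of node embeddings and of the `L_A` output
#'   (default 64).
#' @param dropout Dropout probability applied to node embeddings at the
#'   output of each update layer during training (default 0.1; inverted
#'   scaling, so evaluation needs no rescaling).
#' @param seed Optional integer seed recorded in the parameter object and
#'   used for initialization.
#' @return A `bgnn_params` object: `config` plus per-layer `Wa, ba, Wb, bb`
#'   and head `W1, b1, W2, b2`.
#' @export
bgnn_params <- function(m1, n_layers = 3, hidden = 64, dropout = 0.1,
                        seed = NULL) {
  stopifnot(m1 >= 1, n_layers >= 1, hidden >= 1, dropout >= 0, dropout < 1)
  if (!is.null(seed)) set.seed(seed)

  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    d_v <- if (l == 1L) m1 else hidden
    d_e <- edge_dim(l - 1L, hidden)
    layers[[l]] <- list(
      Wa = glorot(d_v + d_e, hidden), ba = numeric(hidden),
      Wb = glorot(hidden + d_v, hidden), bb = numeric(hidden),
      p = dropout
    )
  }
  head <- list(
    W1 = glorot(2L * hidden, hidden), b1 = numeric(hidden),
    W2 = glorot(hidden, 1L), b2 = 0
  )
  structure(list(
    config = list(m1 = m1, n_layers = n_layers, hidden = hidden,
                  dropout = dropout, seed = seed),
    layers = layers, head = head
  ), class = "bgnn_params")
}

# edge embedding dimension after l update layers
edge_dim <- function(l, hidden) if (l == 0L) 1L else 2L * hidden * l + 1L

#' @export
print.bgnn_params <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(rapply(x[c("layers", "head")], length, how = "unlist"),
                      identity, numeric(1)))
  cat(sprintf(
    "# bgnn_params: %d update layers, hidden %d, dropout %.2f, %d feature nodes (%d parameters)\n",
    cfg$n_layers, cfg$hidden, cfg$dropout, cfg$m1, n_par))
  invisible(x)
}

relu <- function(z) z * (z > 0)

# inverted dropout: zero with prob p, scale survivors by 1/(1-p)
dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

#' Initial graph state
#'
#' Packs a graph's node initializations and edge weights into the layer-0
#' state consumed by [graph_update_layer()]: `Vo` (`n x m1` observation-node
#' embeddings), `Vf` (`m1 x m1` one-hot feature-node embeddings), `E`
#' (`n*m1 x 1` edge embeddings, edges ordered observation-fastest), and the
#' endpoint index vectors `oidx`, `fidx`.
#'
#' @param graph A `bipartite_graph`.
#' @return A `bgnn_state` list.
#' @export
bgnn_state <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  structure(list(
    Vo = graph$obs_init,
    Vf = graph$feat_init,
    E = matrix(as.vector(graph$weights), ncol = 1L),
    oidx = rep(seq_len(graph$n), graph$m1),
    fidx = rep(seq_len(graph$m1), each = graph$n),
    layer = 0L
  ), class = "bgnn_state")
}

#' One graph update layer
#'
#' Updates every node from its incident edges, then every edge from its
#' endpoints. For node `i` with neighborhood \eqn{\varphi_i}:
#' \deqn{V_i^{l+1} = L_B\big(\mathrm{Con}\big[\textstyle\sum_{j \in \varphi_i}
#'   L_A(\mathrm{Con}[V_j^l, e_{ij}^l]),\; V_i^l\big]\big)}
#' with ReLU after both transforms, followed (in training) by inverted
#' dropout on the node embeddings. The neighbor aggregate is divided by the
#' neighborhood size \eqn{|\varphi_i|}: in a complete bipartite graph this is
#' a per-node-type constant (`m+1` for observation nodes, `n` for feature
#' nodes), so the normalization is exactly the plain sum with the constant
#' absorbed into `L_B` — same model class, far better numerical conditioning
#' at initialization. Then every edge grows by concatenation:
#' \deqn{e_{ij}^{l+1} = \mathrm{Con}[V_i^{l+1},\, V_j^{l+1},\, e_{ij}^l].}
#' The graph is complete, so zero-weight (missing) edges participate in the
#' neighbor sum like any other edge.
#'
#' @param state A `bgnn_state` from [bgnn_state()] or a previous layer.
#' @param layer One element of `bgnn_params$layers`.
#' @param training Apply dropout? (default `FALSE`).
#' @return The updated `bgnn_state`.
#' @export
graph_update_layer <- function(state, layer, training = FALSE) {
  Vo <- state$Vo; Vf <- state$Vf; E <- state$E
  oidx <- state$oidx; fidx <- state$fidx
  if (ncol(Vf) + ncol(E) != nrow(layer$Wa)) {
    stop(sprintf("dimension mismatch: layer expects L_A input %d, state has %d",
                 nrow(layer$Wa), ncol(Vf) + ncol(E)), call. = FALSE)
  }

  # messages toward observation nodes (from feature endpoints) and vice versa;
  # the aggregate over the (complete) neighborhood is degree-normalized: the
  # neighborhood size is constant per node type, so this equals the plain sum
  # with the constant absorbed into L_B, but keeps activations well scaled
  Mo <- relu(sweep(cbind(Vf[fidx, , drop = FALSE], E) %*% layer$Wa, 2, layer$ba, "+"))
  Mf <- relu(sweep(cbind(Vo[oidx, , drop = FALSE], E) %*% layer$Wa, 2, layer$ba, "+"))
  So <- unname(rowsum(Mo, oidx, reorder = TRUE)) / nrow(Vf)
  Sf <- unname(rowsum(Mf, fidx, reorder = TRUE)) / nrow(Vo)

  Vo1 <- relu(sweep(cbind(So, Vo) %*% layer$Wb, 2, layer$bb, "+"))
  Vf1 <- relu(sweep(cbind(Sf, Vf) %*% layer$Wb, 2, layer$bb, "+"))
  if (training && layer$p > 0) {
    mo <- dropout_mask(nrow(Vo1), ncol(Vo1), layer$p)
    mf <- dropout_mask(nrow(Vf1), ncol(Vf1), layer$p)
    Vo1 <- Vo1 * mo
    Vf1 <- Vf1 * mf
  }
  E1 <- cbind(Vo1[oidx, , drop = FALSE], Vf1[fidx, , drop = FALSE], E)

  state$Vo <- Vo1; state$Vf <- Vf1; state$E <- E1
  state$layer <- state$layer + 1L
  state
}

#' Run all update layers
#'
#' Applies every graph update layer in sequence to a graph's initial state.
#'
#' @param graph A `bipartite_graph`.
#' @param params A `bgnn_params`.
#' @param training Apply dropout? (default `FALSE`).
#' @return The final `bgnn_state`.
#' @export
bgnn_forward <- function(graph, params, training = FALSE) {
  stopifnot(inherits(params, "bgnn_params"))
  state <- bgnn_state(graph)
  for (layer in params$layers) {
    state <- graph_update_layer(state, layer, training = training)
  }
  state
}

#' Decode cell values from node embeddings
#'
#' The prediction head maps the concatenated final embeddings of an
#' observation node and a feature node through two fully connected layers to
#' a scalar — the model's estimate of that cell of the table. The same head
#' serves missing-trait imputation (feature columns) and yield prediction
#' (the yield column).
#'
#' @param state Final `bgnn_state` from [bgnn_forward()].
#' @param pairs Two-column integer matrix of (observation, feature) index
#'   pairs.
#' @param head The `head` element of a `bgnn_params`.
#' @return Numeric vector of predictions, one per pair.
#' @export
predict_pairs <- function(state, pairs, head) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs[, 1] < 1L) || any(pairs[, 1] > nrow(state$Vo)) ||
      any(pairs[, 2] < 1L) || any(pairs[, 2] > nrow(state$Vf))) {
    stop("pair index out of range", call. = FALSE)
  }
  H <- cbind(state$Vo[pairs[, 1], , drop = FALSE],
             state$Vf[pairs[, 2], , drop = FALSE])
  Z1 <- relu(sweep(H %*% head$W1, 2, head$b1, "+"))
  unname(drop(sweep(Z1 %*% head$W2, 2, head$b2, "+")))
}

#' Full forward pass: imputed table plus yield predictions
#'
#' Runs the update layers in evaluation mode and decodes every unobserved
#' cell and every yield cell. Observed cells pass through unchanged in the
#' returned matrix.
#'
#' @param graph A `bipartite_graph`.
#' @param params A `bgnn_params`.
#' @return A list: `values` (`n x m1` matrix, observed cells as input,
#'   missing cells imputed — standardized scale), `yield` (length-`n` vector
#'   of yield predictions for every row, or `NULL` for a trait-only graph).
#' @export
bgnn_impute <- function(graph, params) {
  state <- bgnn_forward(graph, params, training = FALSE)
  vals <- graph$weights
  miss <- which(!graph$supervised, arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    vals[miss] <- predict_pairs(state, miss, params$head)
  }
  yield <- NULL
  if (graph$has_yield) {
    yield <- predict_pairs(state, cbind(seq_len(graph$n), graph$m1), params$head)
  }
  colnames(vals) <- graph$feat_names
  list(values = vals, yield = yield)
}

#' Save / load model parameters
#'
#' The checkpoint is a single JSON document holding the configuration
#' snapshot (layer count, widths, dropout, seed) and every weight at full
#' precision; `read_bgnn()` restores an identical `bgnn_params`.
#'
#' @param params A `bgnn_params`.
#' @param path Output path (JSON).
#' @return `path` invisibly; `read_bgnn()` returns the `bgnn_params`.
#' @export
write_bgnn <- function(params, path) {
  payload <- list(
    config = params$config,
    layers = purrr::map(params$layers, function(l) {
      list(Wa = l$Wa, ba = l$ba, Wb = l$Wb, bb = l$bb, p = l$p)
    }),
    head = params$head
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_bgnn
#' @export
read_bgnn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = TRUE,
                                 simplifyDataFrame = FALSE)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)
  layers <- purrr::map(seq_len(payload$config$n_layers), function(l) {
    ll <- payload$layers[[l]]
    list(Wa = as_mat(ll$Wa), ba = as.numeric(ll$ba),
         Wb = as_mat(ll$Wb), bb = as.numeric(ll$bb), p = ll$p)
  })
  head <- list(W1 = as_mat(payload$head$W1), b1 = as.numeric(payload$head$b1),
               W2 = matrix(as.numeric(payload$head$W2), ncol = 1L),
               b2 = as.numeric(payload$head$b2))
  cfg <- payload$config
  if (is.null(cfg$seed)) cfg["seed"] <- list(NULL)
  structure(list(config = cfg, layers = layers, head = head),
            class = "bgnn_params")
}
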
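# Independent loop-based implementations used as oracles. These deliberately
# avoid the package's vectorized code paths: everything is per-node /
# per-edge nested loops over an edge list stored as a data frame.

oracle_relu <- function(z) ifelse(z > 0, z, 0)

# forward pass over a bipartite graph, one node and one edge at a time
oracle_forward <- function(graph, params) {
  n <- graph$n; m1 <- graph$m1
  Vo <- lapply(seq_len(n), function(i) graph$obs_init[i, ])
  Vf <- lapply(seq_len(m1), function(j) graph$feat_init[j, ])
  E <- vector("list", n * m1)
  for (j in seq_len(m1)) for (i in seq_len(n)) {
    E[[(j - 1) * n + i]] <- graph$weights[i, j]
  }
  eidx <- function(i, j) (j - 1) * n + i

  for (layer in params$layers) {
    Vo_new <- vector("list", n); Vf_new <- vector("list", m1)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(m1)) {
        msg <- oracle_relu(drop(c(Vf[[j]], E[[eidx(i, j)]]) %*% layer$Wa) + layer$ba)
        s <- s + msg
      }
      s <- s / m1
      Vo_new[[i]] <- oracle_relu(drop(c(s, Vo[[i]]) %*% layer$Wb) + layer$bb)
    }
    for (j in seq_len(m1)) {
      s <- 0
      for (i in seq_len(n)) {
        msg <- oracle_relu(drop(c(Vo[[i]], E[[eidx(i, j)]]) %*% layer$Wa) + layer$ba)
        s <- s + msg
      }
      s <- s / n
      Vf_new[[j]] <- oracle_relu(drop(c(s, Vf[[j]]) %*% layer$Wb) + layer$bb)
    }
    E_new <- vector("list", n * m1)
    for (j in seq_len(m1)) for (i in seq_len(n)) {
      E_new[[eidx(i, j)]] <- c(Vo_new[[i]], Vf_new[[j]], E[[eidx(i, j)]])
    }
    Vo <- Vo_new; Vf <- Vf_new; E <- E_new
  }
  list(Vo = Vo, Vf = Vf, E = E)
}

oracle_predict_pair <- function(oracle_state, i, j, head) {
  hcat <- c(oracle_state$Vo[[i]], oracle_state$Vf[[j]])
  z1 <- oracle_relu(drop(hcat %*% head$W1) + head$b1)
  drop(z1 %*% head$W2) + head$b2
}

# loop-based metrics
oracle_metrics <- function(pred, true) {
  n <- length(pred)
  sae <- 0; sse <- 0
  for (i in seq_len(n)) {
    sae <- sae + abs(pred[i] - true[i])
    sse <- sse + (pred[i] - true[i])^2
  }
  ybar <- sum(true) / n
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (ybar - true[i])^2
  list(mae = sae / n, rmse = sqrt(sse / n), r2 = 1 - sse / sst)
}

# a random encoded, standardized-ish table and its graph, for model tests
random_graph <- function(n, m1, missing_frac = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- matrix(rnorm(n * m1), n, m1)
  vals[runif(n * m1) < missing_frac] <- NA
  # keep at least one observed cell per column where possible
  for (j in seq_len(m1)) {
    miss <- which(is.na(vals[, j]))
    need <- min(max(0, 2 - (n - length(miss))), length(miss))
    if (need > 0) vals[miss[seq_len(need)], j] <- rnorm(need)
  }
  df <- tibble::as_tibble(as.data.frame(vals))
  names(df) <- c(paste0("f", seq_len(m1 - 1)), "yield")
  build_bipartite_graph(as_feature_table(df))
}
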
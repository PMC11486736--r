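#' Simulate a multi-environment maize trial table
#'
#' Generates data with the statistical structure the bipartite network
#' exploits: a correlated weather block (equicorrelated Gaussian; the common
#' factor plays the role of shared regional climate), a trait block tied to
#' the weather block (each trait latent loads on one weather column with
#' strength `rho`, plus independent noise), categorical traits obtained by
#' quantile-binning their continuous latents into labels `1..n_levels`, and
#' a yield that is a linear plus pairwise-interaction function of selected
#' weather and trait latents plus group-scaled Gaussian noise. Planting
#' location groups are sized by a power law (`size_k` proportional to
#' `k^-group_skew`), emulating the imbalance between densely and sparsely
#' sampled regions.
#'
#' Because every latent is jointly Gaussian, the signal variance — and hence
#' the true yield R-squared — is available in closed form from the
#' configuration; by default the noise scale is calibrated so the true
#' R-squared equals `target_r2`.
#'
#' @param n_samples Number of observations (default 500).
#' @param n_weather Continuous weather features (default 20; named
#'   `wx_mean_*` then `wx_var_*`).
#' @param n_traits Trait features (default 20, named `trait_*`); the last
#'   `n_categorical` of them are label-encoded categoricals with `n_levels`
#'   levels.
#' @param n_categorical,n_levels Categorical trait layout (defaults 5 and 4).
#' @param n_groups,group_skew Number of location groups and power-law
#'   exponent of their sizes (defaults 8 and 1.5).
#' @param group_sizes Optional explicit group sizes (overrides the power
#'   law; must sum to `n_samples`).
#' @param group_noise_mult Optional per-group residual-scale multipliers
#'   (default all 1).
#' @param rho Cross-block correlation strength between each trait latent and
#'   its weather column, in [0, 1) (default 0.6).
#' @param rho_weather Equicorrelation of the weather block (default 0.3).
#' @param target_r2 True yield R-squared to calibrate the noise to (default
#'   0.8); ignored when `sigma_y` is given.
#' @param sigma_y Residual standard deviation on the latent scale; `NULL`
#'   (default) calibrates it from `target_r2`.
#' @param yield_mean,yield_scale Affine map from the latent yield scale to
#'   reported units (defaults 600 and 40, kg/acre semantics).
#' @param missing_rate Fraction of feature cells deleted (default 0.18, the
#'   typical raw-table missingness); 0 disables.
#' @param mechanism `"MCAR"` or `"MNAR"`; see [apply_missingness()].
#' @param seed Integer seed; the same seed reproduces the table bit-for-bit.
#' @return A list:
#'   * `table`: a [feature_table][as_feature_table] with missing cells;
#'   * `truth`: list with `complete` (the table before deletion), `signal`
#'     (noiseless yield in reported units), `deletion_mask` (TRUE = deleted),
#'     `true_r2` (closed form), `sigma_y`, and `config` (every argument,
#'     reusable via [write_fixture()] / `do.call`).
#' @examples
#' sim <- simulate_trial_data(n_samples = 50, seed = 1)
#' mean(is.na(sim$table[ft_feature_names(sim$table)]))
#' @export
simulate_trial_data <- function(n_samples = 500, n_weather = 20, n_traits = 20,
                                n_categorical = 5, n_levels = 4,
                                n_groups = 8, group_skew = 1.5,
                                group_sizes = NULL, group_noise_mult = NULL,
                                rho = 0.6, rho_weather = 0.3,
                                target_r2 = 0.8, sigma_y = NULL,
                                yield_mean = 600, yield_scale = 40,
                                missing_rate = 0.18,
                                mechanism = c("MCAR", "MNAR"), seed = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_samples >= 1, n_weather >= 1, n_traits >= 1,
            n_categorical >= 0, n_categorical <= n_traits, n_levels >= 2,
            n_groups >= 1, n_groups <= n_samples,
            rho >= 0, rho < 1, rho_weather >= 0, rho_weather < 1,
            missing_rate >= 0, missing_rate < 1,
            is.null(target_r2) || (target_r2 > 0 && target_r2 < 1))
  if (!is.null(seed)) set.seed(seed)

  config <- list(
    n_samples = n_samples, n_weather = n_weather, n_traits = n_traits,
    n_categorical = n_categorical, n_levels = n_levels,
    n_groups = n_groups, group_skew = group_skew,
    group_sizes = group_sizes, group_noise_mult = group_noise_mult,
    rho = rho, rho_weather = rho_weather,
    target_r2 = target_r2, sigma_y = sigma_y,
    yield_mean = yield_mean, yield_scale = yield_scale,
    missing_rate = missing_rate, mechanism = mechanism, seed = seed
  )

  # --- group layout --------------------------------------------------------
  if (is.null(group_sizes)) {
    w <- (seq_len(n_groups))^(-group_skew)
    group_sizes <- largest_remainder(n_samples * w / sum(w), n_samples)
  }
  stopifnot(sum(group_sizes) == n_samples, all(group_sizes >= 1))
  if (is.null(group_noise_mult)) group_noise_mult <- rep(1, n_groups)
  stopifnot(length(group_noise_mult) == n_groups)
  groups <- rep(sprintf("loc_%02d", seq_len(n_groups)), group_sizes)

  # --- latent blocks -------------------------------------------------------
  # weather: equicorrelated via a shared factor per row
  G <- stats::rnorm(n_samples)
  X <- sqrt(rho_weather) * G +
    sqrt(1 - rho_weather) * matrix(stats::rnorm(n_samples * n_weather), n_samples)
  # trait latents: load on one weather column each, unit marginal variance
  wmap <- ((seq_len(n_traits) - 1L) %% n_weather) + 1L
  Tlat <- rho * X[, wmap, drop = FALSE] +
    sqrt(1 - rho^2) * matrix(stats::rnorm(n_samples * n_traits), n_samples)

  # --- yield signal --------------------------------------------------------
  eff <- yield_effects(n_weather, n_traits)
  U <- cbind(X, Tlat)
  C <- latent_cov(config)
  s <- drop(U[, eff$lin_idx, drop = FALSE] %*% eff$beta)
  for (t in seq_along(eff$int_a)) {
    a <- eff$int_a[t]; b <- eff$int_b[t]
    s <- s + eff$gamma[t] * (U[, a] * U[, b] - C[a, b])
  }
  var_s <- signal_variance(C, eff)

  mean_g2 <- sum(group_sizes * group_noise_mult^2) / n_samples
  if (is.null(sigma_y)) {
    sigma_y <- sqrt(var_s * (1 - target_r2) / (target_r2 * mean_g2))
  }
  true_r2 <- var_s / (var_s + sigma_y^2 * mean_g2)

  noise <- stats::rnorm(n_samples) * sigma_y * rep(group_noise_mult, group_sizes)
  yield <- yield_mean + yield_scale * (s + noise)

  # --- assemble table ------------------------------------------------------
  n_mean <- ceiling(n_weather / 2)
  wx_names <- c(sprintf("wx_mean_%02d", seq_len(n_mean)),
                sprintf("wx_var_%02d", seq_len(n_weather - n_mean)))
  tr_names <- sprintf("trait_%02d", seq_len(n_traits))
  Tobs <- Tlat
  cat_cols <- if (n_categorical > 0) {
    seq_len(n_traits)[(n_traits - n_categorical + 1L):n_traits]
  } else integer()
  if (length(cat_cols) > 0) {
    breaks <- stats::qnorm(seq(0, 1, length.out = n_levels + 1))
    for (j in cat_cols) {
      Tobs[, j] <- as.numeric(cut(Tlat[, j], breaks = breaks, labels = FALSE,
                                  include.lowest = TRUE))
    }
  }
  data <- tibble::as_tibble(as.data.frame(cbind(X, Tobs)))
  names(data) <- c(wx_names, tr_names)
  data$yield <- yield
  data <- dplyr::bind_cols(tibble::tibble(location = groups), data)

  label_maps <- stats::setNames(
    rep(list(sprintf("level_%d", seq_len(n_levels))), length(cat_cols)),
    tr_names[cat_cols])
  complete <- as_feature_table(data, yield_col = "yield",
                               group_col = "location",
                               categorical = tr_names[cat_cols],
                               label_maps = label_maps)

  if (missing_rate > 0) {
    del <- apply_missingness(complete, rate = missing_rate,
                             mechanism = mechanism)
    table <- del$table
    deletion_mask <- del$mask
  } else {
    table <- complete
    deletion_mask <- matrix(FALSE, n_samples, n_weather + n_traits,
                            dimnames = list(NULL, c(wx_names, tr_names)))
  }

  list(
    table = table,
    truth = list(
      complete = complete,
      signal = yield_mean + yield_scale * s,
      groups = groups,
      deletion_mask = deletion_mask,
      true_r2 = true_r2,
      sigma_y = sigma_y,
      config = config
    )
  )
}

# deterministic rounding of fractional sizes to integers summing to total
largest_remainder <- function(x, total) {
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  pmax(as.integer(base), 1L) -> out
  # guard: bumping zeros to 1 may overshoot; trim from the largest
  while (sum(out) > total) {
    i <- which.max(out)
    out[i] <- out[i] - 1L
  }
  out
}

# fixed yield-effect layout derived from the dimensions
yield_effects <- function(n_weather, n_traits) {
  nw <- min(5L, n_weather); nt <- min(5L, n_traits)
  lin_idx <- c(seq_len(nw), n_weather + seq_len(nt))
  beta <- rep(0.4, nw + nt)
  n_int <- min(3L, n_weather, n_traits - 1L)
  if (n_int > 0) {
    int_a <- seq_len(n_int)                       # weather columns
    int_b <- n_weather + seq_len(n_int) + 1L      # trait latents (offset by 1)
    gamma <- rep(0.3, n_int)
  } else {
    int_a <- int_b <- integer(); gamma <- numeric()
  }
  list(lin_idx = lin_idx, beta = beta, int_a = int_a, int_b = int_b,
       gamma = gamma)
}

# closed-form covariance of the latent vector (weather, trait latents)
latent_cov <- function(config) {
  pw <- config$n_weather; pt <- config$n_traits
  r <- config$rho_weather; rho <- config$rho
  Cw <- matrix(r, pw, pw); diag(Cw) <- 1
  wmap <- ((seq_len(pt) - 1L) %% pw) + 1L
  Cwt <- rho * Cw[, wmap, drop = FALSE]                 # pw x pt
  Ct <- rho^2 * Cw[wmap, wmap, drop = FALSE]
  diag(Ct) <- 1
  rbind(cbind(Cw, Cwt), cbind(t(Cwt), Ct))
}

# Var of linear + centered pairwise-interaction function of a Gaussian
# vector: products of zero-mean Gaussians have zero covariance with linear
# terms, and Cov(Ua*Ub, Uc*Ud) = C_ac C_bd + C_ad C_bc
signal_variance <- function(C, eff) {
  b <- numeric(nrow(C)); b[eff$lin_idx] <- eff$beta
  v <- drop(t(b) %*% C %*% b)
  nt <- length(eff$int_a)
  for (t1 in seq_len(nt)) for (t2 in seq_len(nt)) {
    a1 <- eff$int_a[t1]; b1 <- eff$int_b[t1]
    a2 <- eff$int_a[t2]; b2 <- eff$int_b[t2]
    v <- v + eff$gamma[t1] * eff$gamma[t2] *
      (C[a1, a2] * C[b1, b2] + C[a1, b2] * C[b1, a2])
  }
  v
}

#' Delete feature cells at random
#'
#' MCAR deletes each feature cell independently with probability `rate`.
#' MNAR makes deletion probability increase with the cell's standardized
#' value through a logistic link whose intercept is calibrated so the
#' overall expected deletion fraction still equals `rate`. The yield and
#' group columns are never touched.
#'
#' @param x A [feature_table][as_feature_table].
#' @param rate Deletion probability in [0, 1).
#' @param mechanism `"MCAR"` (default) or `"MNAR"`.
#' @param strength Slope of the MNAR logistic link (default 2).
#' @param seed Optional seed.
#' @return A list: `table` (with new `NA`s) and `mask` (logical rows x
#'   feature-columns matrix, `TRUE` = deleted by this call).
#' @export
apply_missingness <- function(x, rate, mechanism = c("MCAR", "MNAR"),
                              strength = 2, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  feat <- ft_feature_names(x)
  data <- tibble::as_tibble(x)
  mask <- matrix(FALSE, nrow(x), length(feat), dimnames = list(NULL, feat))
  if (rate == 0) return(list(table = x, mask = mask))

  if (mechanism == "MCAR") {
    p <- matrix(rate, nrow(x), length(feat))
  } else {
    z <- vapply(feat, function(nm) {
      v <- suppressWarnings(as.numeric(data[[nm]]))
      mu <- mean(v, na.rm = TRUE)
      sd0 <- stats::sd(v, na.rm = TRUE)
      if (is.na(sd0) || sd0 == 0) rep(0, length(v)) else (v - mu) / sd0
    }, numeric(nrow(x)))
    z[is.na(z)] <- 0
    a <- stats::uniroot(function(a) mean(stats::plogis(a + strength * z)) - rate,
                        c(-30, 30))$root
    p <- stats::plogis(a + strength * z)
  }
  draw <- matrix(stats::runif(nrow(x) * length(feat)), nrow(x))
  observed_before <- !is.na(as.matrix(data[, feat]))
  mask <- draw < p & observed_before
  for (k in seq_along(feat)) data[[feat[k]]][mask[, k]] <- NA
  list(table = ft_replace_data(x, data), mask = mask)
}

#' Write a simulation fixture to disk
#'
#' Emits exactly three files into `dir`: `table.csv` (the table with missing
#' cells), `truth.csv` (the complete table), and `config.yaml` (the
#' generator configuration including the seed — `do.call(simulate_trial_data,
#' read_sim_config(dir))` reproduces the fixture).
#'
#' @param table The `feature_table` with missing cells.
#' @param truth The `truth` element returned by [simulate_trial_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(table, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(table, file.path(dir, "table.csv"))
  write_feature_table(truth$complete, file.path(dir, "truth.csv"))
  yaml::write_yaml(truth$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_sim_config <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg[!vapply(cfg, is.null, logical(1))]
}
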
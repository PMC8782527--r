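# Normalizing-flow variational autoencoder for baseline imputation.
#
# Encoder maps the (temporarily population-filled) baseline state, its
# observation mask, background covariates and baseline age to a Gaussian base
# distribution (mu_z, sigma_z) plus a conditioning vector gamma_z; L RealNVP
# coupling layers transform base samples z0 into the flexible posterior
# sample z; the decoder maps (z, u, t0) to the mean mu_x of a Gaussian whose
# scale is the measurement noise sigma_y. Missing coordinates are imputed by
# decoded samples while observed coordinates keep their observed values.

imputer_init_params <- function(N, B, latent = 20, gz_dim = 10, n_flows = 3,
                                flow_hidden = c(30, 24, 10), enc_hidden = c(95, 70),
                                dec_hidden = 65) {
  stopifnot(latent >= 1)
  enc <- list(
    h1 = nn_dense_init(2 * N + 2 * B + 1, enc_hidden[1]),
    h2 = nn_dense_init(enc_hidden[1], enc_hidden[2]),
    out = nn_dense_init(enc_hidden[2], 2 * latent),
    gz = nn_dense_init(enc_hidden[2], gz_dim)
  )
  idxA <- seq(1, latent, by = 2)
  idxB <- setdiff(seq_len(latent), idxA)
  flows <- vector("list", n_flows)
  for (l in seq_len(n_flows)) {
    # alternate which half is transformed
    a <- if (l %% 2 == 1) idxA else idxB
    b <- setdiff(seq_len(latent), a)
    hl <- flow_hidden[((l - 1) %% length(flow_hidden)) + 1]
    flows[[l]] <- list(
      net = nn_mlp_init(length(a) + gz_dim, hl, 2 * max(length(b), 1L), zero_out = TRUE),
      idx_pass = a, idx_tr = b
    )
  }
  dec <- nn_mlp_init(latent + 2 * B + 1, dec_hidden, N)
  list(enc = enc, flows = flows, dec = dec, latent = latent, gz_dim = gz_dim)
}

#' Encode a (filled) baseline state to the latent base distribution
#'
#' @param y_tilde n x N baseline matrix with missing entries temporarily
#'   population-filled (no `NA`s allowed).
#' @param o0 n x N binary observation mask used as encoder input.
#' @param u,umask n x B background covariates and mask.
#' @param t0 baseline ages (length n or scalar).
#' @param ipars imputer parameters (`imputer_init_params()` layout).
#' @return list with `mu` (n x latent), `sigma` (n x latent, strictly
#'   positive), `gz` (n x gz_dim).
#' @export
encode <- function(y_tilde, o0, u, umask, t0, ipars) {
  if (any(!is.finite(advl(y_tilde)))) {
    stop("encoder input contains non-finite values; fill missing entries first")
  }
  n <- nrow(advl(y_tilde))
  tf <- tfeat(t0)
  if (length(tf) == 1L) tf <- rep(tf, n)
  h <- nn_dense(ad_cbind(y_tilde, o0, u, umask, matrix(tf, ncol = 1L)),
                ipars$enc$h1, "elu")
  h <- nn_dense(h, ipars$enc$h2, "elu")
  out <- nn_dense(h, ipars$enc$out, "linear")
  latent <- ipars$latent
  mu <- ad_cols(out, seq_len(latent))
  sigma <- ad_exp(ad_clamp(ad_mul(ad_cols(out, latent + seq_len(latent)), 0.5),
                           -13.8, 6.9))
  gz <- nn_dense(h, ipars$enc$gz, "linear")
  list(mu = mu, sigma = sigma, gz = gz)
}

#' Push base samples through the coupling flows
#'
#' RealNVP-style conditional coupling layers: alternating halves of the
#' coordinates pass through unchanged while the complementary half is
#' affinely transformed with scale/shift computed from the passing half and
#' the conditioning vector `gamma_z`. Returns the transformed sample and the
#' summed log-Jacobian determinant.
#'
#' @param z0 n x latent base sample.
#' @param gz n x gz_dim conditioning vector.
#' @param ipars imputer parameters.
#' @return list `z` (n x latent), `log_det` (n x 1).
#' @export
flow_push <- function(z0, gz, ipars) {
  n <- nrow(advl(z0))
  z <- z0
  log_det <- matrix(0, n, 1)
  for (fl in ipars$flows) {
    if (length(fl$idx_tr) == 0L) next
    za <- ad_cols(z, fl$idx_pass)
    zb <- ad_cols(z, fl$idx_tr)
    st <- nn_mlp(ad_cbind(za, gz), fl$net, act = "tanh")
    nb <- length(fl$idx_tr)
    s <- ad_clamp(ad_cols(st, seq_len(nb)), -6, 6)
    tsh <- ad_cols(st, nb + seq_len(nb))
    zb2 <- ad_add(ad_mul(zb, ad_exp(s)), tsh)
    log_det <- ad_add(log_det, ad_rowSums(s))
    # reassemble in original coordinate order
    pieces <- vector("list", ncol(advl(z)))
    for (j in seq_along(fl$idx_pass)) pieces[[fl$idx_pass[j]]] <- ad_cols(za, j)
    for (j in seq_along(fl$idx_tr)) pieces[[fl$idx_tr[j]]] <- ad_cols(zb2, j)
    z <- do.call(ad_cbind, pieces)
  }
  list(z = z, log_det = log_det)
}

#' Exact inverse of [flow_push()]
#'
#' @inheritParams flow_push
#' @param z n x latent transformed sample.
#' @return n x latent base sample `z0`.
#' @export
flow_inverse <- function(z, gz, ipars) {
  zc <- advl(z)
  for (fl in rev(ipars$flows)) {
    if (length(fl$idx_tr) == 0L) next
    za <- zc[, fl$idx_pass, drop = FALSE]
    st <- advl(nn_mlp(ad_cbind(za, advl(gz)), fl$net, act = "tanh"))
    nb <- length(fl$idx_tr)
    s <- pmin(pmax(st[, seq_len(nb), drop = FALSE], -6), 6)
    tsh <- st[, nb + seq_len(nb), drop = FALSE]
    zc[, fl$idx_tr] <- (zc[, fl$idx_tr, drop = FALSE] - tsh) * exp(-s)
  }
  zc
}

#' Decode a latent sample to the baseline mean
#'
#' @param z n x latent sample.
#' @param u,umask n x B background covariates and mask.
#' @param t0 baseline ages.
#' @param ipars imputer parameters.
#' @return n x N matrix `mu_x`.
#' @export
decode <- function(z, u, umask, t0, ipars) {
  n <- nrow(advl(z))
  tf <- tfeat(t0)
  if (length(tf) == 1L) tf <- rep(tf, n)
  nn_mlp(ad_cbind(z, u, umask, matrix(tf, ncol = 1L)), ipars$dec)
}

#' Multiple imputation of missing baseline coordinates
#'
#' For each sample: draw z from the flow posterior, decode to `mu_x`, draw
#' `x~0 ~ N(mu_x, sigma_y^2)` and keep observed coordinates:
#' `x0 = o * y0 + (1 - o) * x~0`. Observed coordinates are identical across
#' samples.
#'
#' @param y0 n x N observed baseline (missing entries arbitrary).
#' @param o0 n x N observation mask.
#' @param u,umask background covariates and mask.
#' @param t0 baseline ages.
#' @param ipars imputer parameters.
#' @param sigma_y length-N measurement noise scale.
#' @param stats [population_stats()] used to fill encoder inputs.
#' @param sex optional sex stratum per row.
#' @param n_samples number of imputation draws.
#' @return array n x N x n_samples of imputed baselines.
#' @export
impute <- function(y0, o0, u, umask, t0, ipars, sigma_y, stats, sex = NULL,
                   n_samples = 10) {
  if (n_samples < 1) stop("n_samples must be at least 1")
  y0 <- as.matrix(y0); o0 <- as.matrix(o0)
  n <- nrow(y0); N <- ncol(y0)
  ps <- pop_lookup(stats, if (is.null(sex)) rep(0, n) else sex, t0)
  out <- array(NA_real_, c(n, N, n_samples))
  y0f <- y0; y0f[is.na(y0f)] <- 0
  for (srep in seq_len(n_samples)) {
    fill <- ps$mu + ps$sd * matrix(stats::rnorm(n * N), n, N)
    y_tilde <- o0 * y0f + (1 - o0) * fill
    enc <- encode(y_tilde, o0, u, umask, t0, ipars)
    z0 <- enc$mu + enc$sigma * matrix(stats::rnorm(n * ipars$latent), n, ipars$latent)
    fp <- flow_push(z0, enc$gz, ipars)
    mu_x <- decode(fp$z, u, umask, t0, ipars)
    xt0 <- mu_x + matrix(stats::rnorm(n * N), n, N) * rep(sigma_y, each = n)
    out[, , srep] <- o0 * y0f + (1 - o0) * xt0
  }
  out
}

#' Generate synthetic baseline states from background information
#'
#' Samples the latent prior `z0 ~ N(0, I)`, conditions the flows with
#' `gamma_z` obtained by encoding a fully population-filled input (empty
#' observation mask), and decodes as in [impute()] with nothing observed.
#'
#' @inheritParams impute
#' @return array n x N x n_samples of synthetic baselines.
#' @export
generate_baseline <- function(u, umask, t0, ipars, sigma_y, stats, sex = NULL,
                              n_samples = 1) {
  n <- nrow(as.matrix(u))
  N <- length(sigma_y)
  if (n_samples < 1) return(array(NA_real_, c(n, N, 0)))
  out <- array(NA_real_, c(n, N, n_samples))
  o0 <- matrix(0, n, N)
  ps <- pop_lookup(stats, if (is.null(sex)) rep(0, n) else sex, t0)
  for (srep in seq_len(n_samples)) {
    fill <- ps$mu + ps$sd * matrix(stats::rnorm(n * N), n, N)
    enc <- encode(fill, o0, u, umask, t0, ipars)
    z0 <- matrix(stats::rnorm(n * ipars$latent), n, ipars$latent)
    fp <- flow_push(z0, enc$gz, ipars)
    mu_x <- decode(fp$z, u, umask, t0, ipars)
    out[, , srep] <- mu_x + matrix(stats::rnorm(n * N), n, N) * rep(sigma_y, each = n)
  }
  out
}
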
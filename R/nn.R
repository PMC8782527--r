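# Feed-forward and recurrent building blocks on top of the autodiff tape.
# Parameters live in nested lists of plain matrices; `nn_wrap()` lifts them
# onto an active tape as leaves, `nn_grads()` collects the gradients back in
# the same nested shape.

nn_dense_init <- function(n_in, n_out, rng_scale = NULL, zero = FALSE) {
  s <- rng_scale %||% sqrt(2 / (n_in + n_out))
  W <- if (zero) matrix(0, n_in, n_out) else matrix(stats::rnorm(n_in * n_out, sd = s), n_in, n_out)
  list(W = W, b = rep(0, n_out))
}

nn_dense <- function(x, p, act = c("linear", "elu", "tanh", "sigmoid")) {
  act <- match.arg(act)
  h <- ad_addrow(ad_matmul(x, p$W), p$b)
  switch(act, linear = h, elu = ad_elu(h), tanh = ad_tanh(h), sigmoid = ad_sigmoid(h))
}

# two-layer MLP helper
nn_mlp_init <- function(n_in, hidden, n_out, zero_out = FALSE) {
  layers <- list()
  prev <- n_in
  for (i in seq_along(hidden)) {
    layers[[paste0("h", i)]] <- nn_dense_init(prev, hidden[i])
    prev <- hidden[i]
  }
  layers$out <- nn_dense_init(prev, n_out, zero = zero_out)
  layers
}

nn_mlp <- function(x, p, act = "elu") {
  nh <- length(p) - 1L
  h <- x
  for (i in seq_len(nh)) h <- nn_dense(h, p[[paste0("h", i)]], act)
  nn_dense(h, p$out, "linear")
}

## ---- GRU ----

# single GRU layer parameters: input->3h and hidden->3h packed [r|z|n]
nn_gru_init <- function(n_in, n_h) {
  list(
    Wi = matrix(stats::rnorm(n_in * 3 * n_h, sd = sqrt(1 / n_in)), n_in, 3 * n_h),
    Wh = matrix(stats::rnorm(n_h * 3 * n_h, sd = sqrt(1 / n_h)), n_h, 3 * n_h),
    bi = rep(0, 3 * n_h),
    bh = rep(0, 3 * n_h)
  )
}

# one GRU step; x: B x n_in, h: B x n_h -> new hidden B x n_h
nn_gru_step <- function(x, h, p, n_h) {
  gi <- ad_addrow(ad_matmul(x, p$Wi), p$bi)
  gh <- ad_addrow(ad_matmul(h, p$Wh), p$bh)
  ir <- 1:n_h; iz <- (n_h + 1):(2 * n_h); inn <- (2 * n_h + 1):(3 * n_h)
  r <- ad_sigmoid(ad_add(ad_cols(gi, ir), ad_cols(gh, ir)))
  z <- ad_sigmoid(ad_add(ad_cols(gi, iz), ad_cols(gh, iz)))
  n <- ad_tanh(ad_add(ad_cols(gi, inn), ad_mul(r, ad_cols(gh, inn))))
  # h' = (1 - z) * n + z * h
  ad_add(ad_mul(ad_sub(1, z), n), ad_mul(z, h))
}

## ---- parameter trees ----

# non-trainable metadata fields inside parameter trees
.nn_meta <- c("latent", "gz_dim", "idx_pass", "idx_tr", "n_h1", "n_h2",
              "Mx", "Mv")

.nn_walk <- function(par, leaf_fn) {
  if (!is.list(par)) return(leaf_fn(par))
  out <- par
  nms <- names(par) %||% rep("", length(par))
  for (i in seq_along(par)) {
    if (nms[i] %in% .nn_meta) next
    out[[i]] <- .nn_walk(par[[i]], leaf_fn)
  }
  out
}

nn_wrap <- function(par) .nn_walk(par, ad_leaf)

nn_grads <- function(wrapped) {
  .nn_walk(wrapped, function(nd) {
    g <- nd$g
    if (is.null(g)) {
      v <- nd$v
      g <- if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else rep(0, length(v))
    }
    g
  })
}

nn_adam_init <- function(par) {
  z <- .nn_walk(par, function(p) p * 0)
  list(m = z, v = z, t = 0L)
}

# one ADAM update; returns list(par, state)
nn_adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         clip = 10) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- p
      mo <- m; vo <- v
      nms <- names(p) %||% rep("", length(p))
      for (i in seq_along(p)) {
        if (nms[i] %in% .nn_meta) next
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        out[[i]] <- r$p; mo[[i]] <- r$m; vo[[i]] <- r$v
      }
      return(list(p = out, m = mo, v = vo))
    }
    g <- pmin(pmax(g, -clip), clip)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(par, grad, state$m, state$v)
  list(par = out$p, state = list(m = out$m, v = out$v, t = t))
}
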
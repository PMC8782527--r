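# Shared fixtures built in code.

# tiny deterministic cohort: n individuals, N vars, complete data
toy_cohort <- function(n = 4, N = 2, B = 2, K = 3, seed = 1) {
  set.seed(seed)
  t0 <- runif(n, 68, 80)
  times <- lapply(seq_len(n), function(m) t0[m] + seq(0, by = 2, length.out = K))
  y <- lapply(seq_len(n), function(m) matrix(rnorm(K * N), K, N))
  o <- lapply(seq_len(n), function(m) matrix(1, K, N))
  ac <- lapply(seq_len(n), function(m) {
    if (m %% 2 == 0) list(a = max(times[[m]]), c = 1L)
    else list(a = max(times[[m]]) + 1, c = 0L)
  })
  new_cohort(
    id = paste0("i", seq_len(n)), t0 = t0, times = times, y = y, o = o,
    u = cbind(rbinom(n, 1, 0.5), rnorm(n)), umask = matrix(1, n, B),
    a = vapply(ac, `[[`, numeric(1), "a"), c = vapply(ac, `[[`, integer(1), "c")
  )
}

# constant-hazard ground truth for closed-form checks
const_truth <- function(N = 1, theta = 0.3, sigma = 0.2, lambda0 = 0,
                        meas_sd = 0, miss = 0, gap = 2) {
  structure(
    list(W = matrix(0, N, N), rate = rep(theta, N), eq = rep(0, N),
         sigma_x = rep(sigma, N), measurement_sd = rep(meas_sd, N),
         h0 = if (lambda0 > 0) log(lambda0) else -30, h_age = 0,
         h_x = rep(0, N), missing_rates = rep(miss, N), visit_gap_mean = gap),
    class = "ground_truth"
  )
}

# minimal prediction object on a common grid (for metric tests)
toy_pred <- function(S, tau, t0, a, c, s = NULL, source = NULL) {
  list(S = S, tau = tau, t0 = t0, a = a, c = c,
       s = s %||% rep(1, length(a)),
       source = source %||% as.character(seq_along(a)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive pair-enumeration oracle for the time-dependent concordance
oracle_cindex <- function(S, tau, t0, a, c, s, source) {
  n <- length(a)
  Sfun <- function(m, t) approx(t0[m] + tau, S[m, ], xout = t, yleft = 1,
                                yright = S[m, ncol(S)])$y
  num <- den <- 0
  for (m1 in seq_len(n)) for (m2 in seq_len(n)) {
    if (m1 == m2 || source[m1] == source[m2]) next
    if (c[m1] != 0 || !(a[m1] < a[m2])) next
    w <- s[m1] * s[m2]
    den <- den + w
    if (Sfun(m1, a[m1]) < Sfun(m2, a[m1])) num <- num + w
  }
  if (den == 0) NA_real_ else num / den
}

# direct-sum oracle for the IPCW Brier score
oracle_brier <- function(S, tau, t0, a, c, s, t) {
  n <- length(a)
  km <- survival::survfit(survival::Surv(a, c == 1) ~ 1)
  G <- function(x, minus = FALSE) {
    idx <- if (minus) which(km$time < x - 1e-12) else which(km$time <= x + 1e-12)
    if (!length(idx)) 1 else km$surv[max(idx)]
  }
  tot <- w <- 0
  for (m in seq_len(n)) {
    St <- approx(t0[m] + tau, S[m, ], xout = t, yleft = 1,
                 yright = S[m, ncol(S)])$y
    if (a[m] <= t && c[m] == 0) {
      g <- G(a[m], minus = TRUE)
      if (g > 0) { tot <- tot + s[m] * St^2 / g; w <- w + s[m] }
    } else if (a[m] > t) {
      g <- G(t)
      if (g > 0) { tot <- tot + s[m] * (1 - St)^2 / g; w <- w + s[m] }
    } else {
      w <- w + s[m]
    }
  }
  tot / w
}

# random small prediction sets for property sweeps
rand_pred <- function(n, seed) {
  set.seed(seed)
  tau <- seq(0, 10, by = 0.5)
  S <- t(apply(matrix(runif(n * length(tau), 0, 0.15), n), 1,
               function(r) exp(-cumsum(r))))
  S[, 1] <- 1
  t0 <- runif(n, 65, 80)
  a <- t0 + runif(n, 0.5, 9.5)
  c <- rbinom(n, 1, 0.4)
  s <- runif(n, 0.3, 1)
  toy_pred(S, tau, t0, a, c, s)
}

# maximum relative error between the tape gradient of the batched objective
# and central finite differences, over a spread of parameter groups
elbo_gradcheck <- function(seed = 77) {
  set.seed(seed)
  truth <- sample_ground_truth(2, 0.3)
  ch <- simulate_cohort(truth, M = 5, horizon = 4, dt = 0.1)
  cfg <- trajnet_config(latent = 4, n_flows = 2, dt = 0.5, seed = 1)
  prep <- trajnet:::tn_prepare(ch, cfg)
  st <- population_stats(ch)
  par <- trajnet:::tn_init_params(2, 2, cfg)
  par$f$V <- matrix(rnorm(length(par$f$V), sd = 0.2), nrow(par$f$V)) * par$f$Mv
  par$g$out$W <- matrix(rnorm(length(par$g$out$W), sd = 0.2), nrow(par$g$out$W))
  par$sig$out$W <- matrix(rnorm(length(par$sig$out$W), sd = 0.2),
                          nrow(par$sig$out$W))
  par$haz$head$W <- matrix(rnorm(10, sd = 0.3), 10, 1)
  set.seed(seed + 1)
  draws <- trajnet:::tn_draw_noise(prep, cfg, st)
  betas <- c(beta_xz = 0.7, beta_W = 0.8)
  loss_at <- function(p) trajnet:::tn_loss(p, prep, betas, draws, cfg, 5, TRUE)$loss
  trajnet:::ad_tape_begin()
  parw <- trajnet:::nn_wrap(par)
  res <- trajnet:::tn_loss(parw, prep, betas, draws, cfg, 5, TRUE)
  trajnet:::ad_backward(res$loss)
  grads <- trajnet:::nn_grads(parw)
  trajnet:::ad_tape_end()
  checks <- list(
    c("W_bar", NA), c("log_b", NA), c("log_alpha", NA), c("log_beta", NA),
    c("f", "Wx"), c("f", "V"), c("g", "out"), c("sig", "h1"),
    c("haz", "head"), c("haz", "gru1")
  )
  eps <- 1e-5
  worst <- 0
  for (chk in checks) {
    getp <- function(p) if (is.na(chk[2])) p[[chk[1]]] else p[[chk[1]]][[chk[2]]]
    g_ref <- getp(grads)
    while (is.list(g_ref)) g_ref <- g_ref[[1]]
    ii <- which(abs(g_ref) == max(abs(g_ref)))[1]
    mod <- function(p, delta) {
      t2 <- getp(p)
      if (is.list(t2)) t2[[1]][ii] <- t2[[1]][ii] + delta else t2[ii] <- t2[ii] + delta
      if (is.na(chk[2])) p[[chk[1]]] <- t2 else p[[chk[1]]][[chk[2]]] <- t2
      p
    }
    fd <- (loss_at(mod(par, eps)) - loss_at(mod(par, -eps))) / (2 * eps)
    denom <- max(abs(g_ref[ii]) + abs(fd), 1e-6)
    worst <- max(worst, abs(g_ref[ii] - fd) / denom)
  }
  worst
}
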
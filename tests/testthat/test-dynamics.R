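make_pars <- function(N = 3, B = 2, zero_f = TRUE, seed = 1) {
  set.seed(seed)
  cfg <- trajnet_config(latent = 4, n_flows = 2)
  par <- trajnet:::tn_init_params(N, B, cfg)
  if (!zero_f) {
    par$f$V <- matrix(rnorm(length(par$f$V), sd = 0.3), nrow(par$f$V)) * par$f$Mv
  }
  par
}

test_that("prior drift is the linear coupling plus self-dynamics", {
  N <- 3; n <- 5
  par <- make_pars(N)
  x <- matrix(rnorm(n * N), n, N)
  u <- matrix(rnorm(n * 2), n, 2); um <- matrix(1, n, 2)
  W0 <- matrix(0, N, N)
  expect_equal(prior_drift(x, 75, u, um, W0, par), matrix(0, n, N))
  # linearity: perturbing x_j changes drift_i by exactly W_ij * delta
  W <- matrix(rnorm(N * N, sd = 0.3), N, N); diag(W) <- 0
  d0 <- prior_drift(x, 75, u, um, W, par)
  x2 <- x; x2[, 2] <- x2[, 2] + 0.37
  d1 <- prior_drift(x2, 75, u, um, W, par)
  expect_equal(d1[, 1] - d0[, 1], rep(W[1, 2] * 0.37, n))
  expect_equal(d1[, 3] - d0[, 3], rep(W[3, 2] * 0.37, n))
  expect_error(prior_drift(x[, 1:2], 75, u, um, W, par), "mismatch")
})

test_that("finite-difference Jacobian off-diagonals recover W", {
  N <- 3
  par <- make_pars(N, zero_f = FALSE, seed = 4)
  W <- matrix(rnorm(N * N, sd = 0.3), N, N); diag(W) <- 0
  x <- matrix(rnorm(N), 1, N)
  u <- matrix(0, 1, 2); um <- matrix(1, 1, 2)
  eps <- 1e-6
  J <- matrix(0, N, N)
  for (j in seq_len(N)) {
    xp <- x; xp[1, j] <- xp[1, j] + eps
    xm <- x; xm[1, j] <- xm[1, j] - eps
    J[, j] <- (prior_drift(xp, 75, u, um, W, par) -
               prior_drift(xm, 75, u, um, W, par)) / (2 * eps)
  }
  off <- row(W) != col(W)
  expect_lt(max(abs(J[off] - W[off])), 1e-5)
})

test_that("posterior drift reduces to prior drift when g vanishes", {
  N <- 3; n <- 4
  par <- make_pars(N, zero_f = FALSE, seed = 2)  # g is zero-initialized
  x <- matrix(rnorm(n * N), n, N)
  u <- matrix(rnorm(n * 2), n, 2); um <- matrix(1, n, 2)
  W <- matrix(rnorm(N * N, sd = 0.2), N, N); diag(W) <- 0
  expect_equal(posterior_drift(x, 75, u, um, W, par),
               prior_drift(x, 75, u, um, W, par))
  # with a random g, the difference is exactly (Wbar - W) x + g
  par$g$out$W <- matrix(rnorm(8 * N, sd = 0.2), 8, N)
  Wb <- W + matrix(rnorm(N * N, sd = 0.05), N, N); diag(Wb) <- 0
  gv <- trajnet:::drift_g(x, 75, u, um, par$g)
  expect_equal(posterior_drift(x, 75, u, um, Wb, par) -
                 prior_drift(x, 75, u, um, W, par),
               x %*% t(Wb - W) + gv)
})

test_that("the integrator is exact for zero drift and noise", {
  N <- 2
  x0 <- matrix(rnorm(6), 3, N)
  sim <- sde_integrate(x0, 70, horizon = 5, dt = 0.5,
                       drift = function(x, t) 0 * trajnet:::advl(x),
                       diffusion = function(x, t) 0 * trajnet:::advl(x))
  expect_equal(sim$xs[[length(sim$xs)]], x0)
})

test_that("zero-noise linear dynamics match the matrix exponential", {
  set.seed(6)
  N <- 3
  A <- matrix(rnorm(N * N, sd = 0.25), N, N)
  diag(A) <- -0.4
  x0 <- matrix(rnorm(N), 1, N)
  Tend <- 5
  xT_true <- as.vector(Matrix::expm(A * Tend) %*% t(x0))
  err <- vapply(c(0.5, 0.05), function(dt) {
    sim <- sde_integrate(x0, 70, horizon = Tend, dt = dt,
                         drift = function(x, t) trajnet:::advl(x) %*% t(A),
                         diffusion = function(x, t) 0 * trajnet:::advl(x))
    max(abs(sim$xs[[length(sim$xs)]] - xT_true))
  }, numeric(1))
  expect_lt(err[1], 1e-3)
  expect_lt(err[2], 1e-5)
})

test_that("strong error decays at order ~1 on a solvable scalar SDE", {
  # geometric-type SDE dx = a x dt + b x dW with exact strong solution
  a <- -0.3; b <- 0.4; Tend <- 4; n_paths <- 4000
  set.seed(11)
  dt_f <- 0.125
  n_f <- Tend / dt_f
  dWf <- lapply(seq_len(n_f), function(k) matrix(rnorm(n_paths, sd = sqrt(dt_f)),
                                                 n_paths, 1))
  W_T <- Reduce(`+`, dWf)
  x0 <- matrix(1, n_paths, 1)
  x_exact <- exp((a - b^2 / 2) * Tend + b * W_T)
  errs <- vapply(c(0.5, 0.25, 0.125), function(dt) {
    agg <- as.integer(dt / dt_f)
    dW <- lapply(seq_len(Tend / dt), function(k) {
      Reduce(`+`, dWf[((k - 1) * agg + 1):(k * agg)])
    })
    sim <- sde_integrate(x0, 0, horizon = Tend, dt = dt, dW = dW,
                         drift = function(x, t) a * trajnet:::advl(x),
                         diffusion = function(x, t) b * trajnet:::advl(x))
    mean(abs(sim$xs[[length(sim$xs)]] - x_exact))
  }, numeric(1))
  slope <- coef(lm(log2(errs) ~ log2(c(0.5, 0.25, 0.125))))[2]
  expect_gte(slope, 0.8)
})

test_that("prior and posterior paths coincide when W_bar = W and g = 0", {
  N <- 2
  par <- make_pars(N, zero_f = FALSE, seed = 3)
  W <- matrix(c(0, 0.2, -0.3, 0), N, N)
  par$W_bar <- W
  x0 <- matrix(rnorm(8), 4, N)
  u <- matrix(rnorm(8), 4, 2); um <- matrix(1, 4, 2)
  set.seed(9)
  dW <- lapply(1:10, function(k) matrix(rnorm(8, sd = sqrt(0.5)), 4, N))
  sim_pr <- sde_integrate(x0, 70, u, um, par, horizon = 5, dt = 0.5,
                          mode = "prior", W = W, dW = dW)
  sim_po <- sde_integrate(x0, 70, u, um, par, horizon = 5, dt = 0.5,
                          mode = "posterior", dW = dW)
  expect_equal(sim_po$xs[[11]], sim_pr$xs[[11]])
})

test_that("latent drift variants have the right shape and degenerate limits", {
  B <- 2
  p1 <- latent_init(1, B, zero = TRUE)
  z <- matrix(rnorm(5), 5, 1)
  u <- matrix(rnorm(10), 5, 2); um <- matrix(1, 5, 2)
  d <- latent_drift(z, 75, u, um, p1)
  expect_equal(dim(d), c(5, 1))
  expect_equal(d, matrix(0, 5, 1))
  set.seed(14)
  p3 <- latent_init(3, B, summary_1d = TRUE)
  z3 <- matrix(rnorm(15), 5, 3)
  d3a <- latent_drift(z3, 75, u, um, p3, summary_1d = TRUE)
  u2 <- matrix(rnorm(10), 5, 2)
  d3b <- latent_drift(z3, 75, u2, um, p3, summary_1d = TRUE)
  expect_equal(d3a, d3b)  # background covariates removed from the drift input
  pl <- latent_init(2, B)
  set.seed(20)
  sim1 <- sde_integrate(matrix(0, 2, 2), 70, horizon = 3, dt = 0.5,
                        drift = function(x, t) latent_drift(x, t, u[1:2, ], um[1:2, ], pl),
                        diffusion = function(x, t) matrix(0.1, 2, 2),
                        dW = lapply(1:6, function(k) matrix(rnorm(4, sd = sqrt(0.5)), 2, 2)))
  set.seed(20)
  sim2 <- sde_integrate(matrix(0, 2, 2), 70, horizon = 3, dt = 0.5,
                        drift = function(x, t) latent_drift(x, t, u[1:2, ], um[1:2, ], pl),
                        diffusion = function(x, t) matrix(0.1, 2, 2),
                        dW = lapply(1:6, function(k) matrix(rnorm(4, sd = sqrt(0.5)), 2, 2)))
  expect_equal(sim1$xs[[7]], sim2$xs[[7]])
})
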
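test_that("masked Gaussian log-likelihood counts only observed entries", {
  y <- matrix(rnorm(6), 2, 3)
  x <- matrix(rnorm(6), 2, 3)
  expect_equal(obs_loglik(y, matrix(0, 2, 3), x, rep(1, 3)), 0)
  o <- matrix(0, 2, 3); o[1, 1] <- 1
  expect_equal(obs_loglik(x, o, x, rep(1, 3)), -0.5 * log(2 * pi))
  o2 <- o; o2[2, 2] <- 0  # already unobserved: no change
  expect_equal(obs_loglik(y, o, x, rep(1, 3)), obs_loglik(y, o2, x, rep(1, 3)))
  expect_error(obs_loglik(y, o, x, c(1, -1, 1)), "positive")
})

test_that("survival log-likelihood matches closed forms for constant hazard", {
  lam0 <- 0.08; t0 <- 70
  tms <- seq(t0, t0 + 30, by = 0.001)
  curve <- survival_curve(rep(lam0, length(tms)), tms)
  # censored at a: integral of log S = -lam0 * (a - t0)^2 / 2
  a_c <- 75
  expect_equal(survival_loglik(curve, a_c, censored = 1),
               -lam0 * (a_c - t0)^2 / 2, tolerance = 1e-6)
  # uncensored at a with the dead-window penalty
  a_d <- 78; w <- 5
  oracle <- log(lam0) - lam0 * (a_d - t0) +
    integrate(function(t) log(1 - exp(-lam0 * (t - t0))), a_d, a_d + w,
              rel.tol = 1e-10)$value
  expect_equal(survival_loglik(curve, a_d, censored = 0, window = w), oracle,
               tolerance = 1e-5)
  # S == 1 everywhere contributes 0 for a censored individual
  ones <- survival_curve(rep(0, 21), seq(t0, t0 + 10, by = 0.5))
  expect_equal(survival_loglik(ones, t0 + 8, censored = 1), 0)
  # S -> 1 at the death age stays finite through the clamp
  expect_true(is.finite(survival_loglik(ones, t0 + 2, censored = 0)))
})

test_that("the trajectory penalty is a negated weighted path mismatch", {
  N <- 2; T1 <- 11
  tms <- seq(0, 5, by = 0.5)
  X <- matrix(1, T1, N)
  W <- matrix(c(0, 0.3, -0.2, 0), 2, 2)
  g0 <- matrix(0, T1, N)
  expect_equal(path_penalty(X, tms, W, W, g0, matrix(1, T1, N)), 0)
  # constant mismatch m over a length-T path: -||m||^2 T / 2
  m <- c(0.4, -0.1)
  gm <- matrix(rep(-m, each = T1), T1, N)  # mismatch = Wx - Wbar x - g = m
  expect_equal(path_penalty(X, tms, W, W, gm, matrix(1, T1, N)),
               -0.5 * sum(m^2) * 5)
  set.seed(4)
  for (i in 1:20) {
    Xr <- matrix(rnorm(T1 * N), T1, N)
    gr <- matrix(rnorm(T1 * N), T1, N)
    expect_lte(path_penalty(Xr, tms, W, W * 0.5, gr, matrix(0.7, T1, N)), 0)
  }
  expect_error(path_penalty(X, tms, W, W, g0, matrix(0, T1, N)), "nonzero")
})

test_that("Laplace KL matches quadrature and is nonnegative", {
  expect_equal(kl_laplace(0, 0.05, 0.05), 0)
  kl_quad <- function(m, b, s) {
    lim <- abs(m) + 60 * max(b, s)
    integrate(function(x) {
      q <- exp(-abs(x - m) / b) / (2 * b)
      ifelse(q > 0, q * (log(q) + abs(x) / s + log(2 * s)), 0)
    }, -lim, lim, rel.tol = 1e-12)$value
  }
  expect_equal(kl_laplace(0.1, 0.05, 0.05), kl_quad(0.1, 0.05, 0.05),
               tolerance = 1e-6)
  expect_equal(kl_laplace(-0.3, 0.01, 0.05), kl_quad(-0.3, 0.01, 0.05),
               tolerance = 1e-6)
  set.seed(9)
  ms <- rnorm(1000, sd = 0.3); bs <- exp(rnorm(1000, -3, 1))
  expect_true(all(kl_laplace(ms, bs) >= 0))
  expect_error(kl_laplace(0, -1), "positive")
})

test_that("Gamma KL matches quadrature and is nonnegative", {
  expect_equal(kl_gamma(1, 25000), 0)
  kl_quad <- function(a, b, a0, b0) {
    integrate(function(x) {
      q <- dgamma(x, a, b)
      ifelse(q > 0,
             q * (dgamma(x, a, b, log = TRUE) - dgamma(x, a0, b0, log = TRUE)),
             0)
    }, 0, qgamma(1 - 1e-14, a, b), rel.tol = 1e-12)$value
  }
  expect_equal(kl_gamma(2, 25000), kl_quad(2, 25000, 1, 25000), tolerance = 1e-6)
  expect_equal(kl_gamma(3, 7, prior = c(2, 5)), kl_quad(3, 7, 2, 5),
               tolerance = 1e-6)
  set.seed(3)
  for (i in 1:20) {
    expect_gte(kl_gamma(exp(rnorm(1)), exp(rnorm(1, 2)), prior = c(1, 5)), 0)
  }
  expect_error(kl_gamma(-1, 2), "positive")
})

test_that("latent KL has its Gaussian closed form minus the flow correction", {
  expect_equal(kl_latent(matrix(0, 2, 3), matrix(1, 2, 3)), 0)
  expect_equal(kl_latent(matrix(1, 1, 1), matrix(1, 1, 1)), 0.5)
  set.seed(5)
  mu <- matrix(rnorm(10), 5, 2); sg <- matrix(exp(rnorm(10)), 5, 2)
  expect_gte(kl_latent(mu, sg), 0)  # before the flow correction
  expect_equal(kl_latent(mu, sg, log_det = matrix(1, 5, 1)),
               kl_latent(mu, sg) - 5)
  expect_error(kl_latent(mu, -sg), "positive")
})

test_that("the annealing schedule ramps the two KL groups in order", {
  cfg <- trajnet_config()
  expect_equal(unname(anneal_schedule(0, cfg)), c(0, 0))
  expect_equal(unname(anneal_schedule(150, cfg)), c(0.5, 0))
  expect_equal(unname(anneal_schedule(300, cfg)), c(1, 0))
  expect_equal(unname(anneal_schedule(400, cfg)), c(1, 0.5))
  expect_equal(unname(anneal_schedule(500, cfg)), c(1, 1))
  expect_equal(unname(anneal_schedule(900, cfg)), c(1, 1))
})

test_that("the batched objective gradient matches finite differences", {
  expect_lt(elbo_gradcheck(seed = 77), 1e-3)
})

test_that("likelihood contributions are linear in the sample weights", {
  set.seed(31)
  truth <- sample_ground_truth(2, 0.3)
  ch <- simulate_cohort(truth, M = 6, horizon = 4, dt = 0.1)
  cfg <- trajnet_config(latent = 4, n_flows = 2, seed = 2)
  prep <- trajnet:::tn_prepare(ch, cfg)
  st <- population_stats(ch)
  par <- trajnet:::tn_init_params(2, 2, cfg)
  set.seed(8)
  draws <- trajnet:::tn_draw_noise(prep, cfg, st)
  betas <- c(beta_xz = 1, beta_W = 1)
  p1 <- trajnet:::tn_loss(par, prep, betas, draws, cfg, 6, TRUE)$parts
  prep2 <- prep; prep2$s <- prep$s * 2
  p2 <- trajnet:::tn_loss(par, prep2, betas, draws, cfg, 6, TRUE)$parts
  expect_equal(p2["obs"], 2 * p1["obs"])
  expect_equal(p2["surv"], 2 * p1["surv"])
  expect_equal(p2["pen"], 2 * p1["pen"])
  expect_equal(p2["klW"], p1["klW"])  # parameter KLs are weight-free
})

test_that("zero-epoch training returns the initialized state unchanged", {
  set.seed(12)
  truth <- sample_ground_truth(2, 0.2)
  ch <- simulate_cohort(truth, M = 12, horizon = 4, dt = 0.1)
  cfg <- trajnet_config(epochs = 0, latent = 4, n_flows = 2, seed = 3)
  fit <- trajnet(ch, config = cfg, replicate = FALSE)
  expect_s3_class(fit, "trajnet")
  expect_equal(nrow(fit$history), 0)
  set.seed(cfg$seed)
  expect_true(all(abs(diag(coef(fit))) < 1e-12))
})
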
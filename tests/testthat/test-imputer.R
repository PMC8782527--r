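imp_pars <- function(N = 4, B = 2, latent = 20, seed = 1, random_flows = FALSE) {
  set.seed(seed)
  ip <- trajnet:::imputer_init_params(N, B, latent = latent)
  if (random_flows) {
    for (l in seq_along(ip$flows)) {
      ip$flows[[l]]$net$out$W <- matrix(rnorm(length(ip$flows[[l]]$net$out$W), sd = 0.3),
                                        nrow(ip$flows[[l]]$net$out$W))
      ip$flows[[l]]$net$out$b <- rnorm(length(ip$flows[[l]]$net$out$b), sd = 0.1)
    }
  }
  ip
}

test_that("the encoder emits the documented latent dimensions", {
  for (N in c(3, 7)) {
    ip <- imp_pars(N = N)
    n <- 5
    y <- matrix(rnorm(n * N), n, N); o <- matrix(1, n, N)
    u <- matrix(rnorm(n * 2), n, 2); um <- matrix(1, n, 2)
    enc <- encode(y, o, u, um, rep(72, n), ip)
    expect_equal(dim(enc$mu), c(n, 20))
    expect_equal(dim(enc$sigma), c(n, 20))
    expect_equal(dim(enc$gz), c(n, 10))
    expect_true(all(enc$sigma > 0))
    enc2 <- encode(y, o, u, um, rep(72, n), ip)
    expect_identical(enc, enc2)
  }
  expect_error(encode(matrix(NA_real_, 1, 3), matrix(0, 1, 3), matrix(0, 1, 2),
                      matrix(1, 1, 2), 70, imp_pars(N = 3)),
               "non-finite")
})

test_that("sigma_z stays positive under random encoder parameters", {
  n <- 20
  for (i in 1:30) {
    ip <- imp_pars(N = 3, seed = i)
    ip$enc$out$W <- matrix(rnorm(length(ip$enc$out$W), sd = 1), nrow(ip$enc$out$W))
    enc <- encode(matrix(rnorm(n * 3, sd = 3), n, 3), matrix(1, n, 3),
                  matrix(rnorm(n * 2), n, 2), matrix(1, n, 2), rep(80, n), ip)
    expect_true(all(enc$sigma > 0))
  }
})

test_that("zero-initialized flows are the identity with zero log-determinant", {
  ip <- imp_pars()
  z0 <- matrix(rnorm(6 * 20), 6, 20)
  gz <- matrix(rnorm(60), 6, 10)
  fp <- flow_push(z0, gz, ip)
  expect_equal(fp$z, z0)
  expect_equal(fp$log_det, matrix(0, 6, 1))
})

test_that("flows invert exactly and match the numerical Jacobian", {
  ip <- imp_pars(latent = 5, random_flows = TRUE, seed = 3)
  z0 <- matrix(rnorm(4 * 5), 4, 5)
  gz <- matrix(rnorm(4 * 10), 4, 10)
  fp <- flow_push(z0, gz, ip)
  expect_lt(max(abs(flow_inverse(fp$z, gz, ip) - z0)), 1e-6)
  # log|det| of the full transform by finite differences, one row at a time
  for (m in 1:2) {
    J <- matrix(0, 5, 5)
    eps <- 1e-6
    for (j in 1:5) {
      zp <- z0[m, , drop = FALSE]; zp[1, j] <- zp[1, j] + eps
      zm <- z0[m, , drop = FALSE]; zm[1, j] <- zm[1, j] - eps
      J[, j] <- (flow_push(zp, gz[m, , drop = FALSE], ip)$z -
                 flow_push(zm, gz[m, , drop = FALSE], ip)$z) / (2 * eps)
    }
    expect_lt(abs(log(abs(det(J))) - fp$log_det[m, 1]), 1e-4)
  }
})

test_that("a coupling layer transforms the base density as its affine law", {
  # conditionally on the passing half, the transformed coordinates of a
  # single coupling layer are exactly N(t, e^{2s}); check by Monte Carlo
  set.seed(8)
  ip <- trajnet:::imputer_init_params(4, 2, latent = 4, n_flows = 1)
  ip$flows[[1]]$net$out$W <- matrix(rnorm(length(ip$flows[[1]]$net$out$W), sd = 0.4),
                                    nrow(ip$flows[[1]]$net$out$W))
  ip$flows[[1]]$net$out$b <- rnorm(length(ip$flows[[1]]$net$out$b), sd = 0.2)
  n <- 2000
  zA <- c(0.7, -1.2)                       # fixed passing coordinates (1, 3)
  gz <- matrix(0.3, n, 10)
  set.seed(22)
  z0 <- matrix(0, n, 4)
  z0[, c(1, 3)] <- matrix(zA, n, 2, byrow = TRUE)
  z0[, c(2, 4)] <- rnorm(2 * n)
  z <- flow_push(z0, gz, ip)$z
  # oracle shift/scale from pushing the special points zB = 0 and zB = 1
  base <- matrix(c(zA[1], 0, zA[2], 0), 1)
  one <- matrix(c(zA[1], 1, zA[2], 1), 1)
  tsh <- flow_push(base, gz[1, , drop = FALSE], ip)$z[, c(2, 4)]
  es <- flow_push(one, gz[1, , drop = FALSE], ip)$z[, c(2, 4)] - tsh
  for (jj in 1:2) {
    j <- c(2, 4)[jj]
    p <- suppressWarnings(ks.test(z[, j], "pnorm", tsh[jj], abs(es[jj])))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("the decoder is deterministic with output length N and live gradients", {
  ip <- imp_pars(N = 6, seed = 5)
  z <- matrix(rnorm(3 * 20), 3, 20)
  u <- matrix(rnorm(6), 3, 2); um <- matrix(1, 3, 2)
  mu1 <- decode(z, u, um, rep(70, 3), ip)
  expect_equal(dim(mu1), c(3, 6))
  expect_identical(mu1, decode(z, u, um, rep(70, 3), ip))
  z2 <- z; z2[1, 3] <- z2[1, 3] + 1e-4
  mu2 <- decode(z2, u, um, rep(70, 3), ip)
  expect_gt(sum(abs(mu2[1, ] - mu1[1, ])), 0)  # non-degenerate in z
})

test_that("imputation keeps observed coordinates bit-identical", {
  N <- 4
  ip <- imp_pars(N = N, seed = 6, random_flows = TRUE)
  ch <- toy_cohort(n = 8, N = N, seed = 2)
  st <- population_stats(ch)
  y0 <- matrix(rnorm(8 * N), 8, N)
  o0 <- matrix(rbinom(8 * N, 1, 0.6), 8, N)
  u <- ch$u; um <- ch$umask
  set.seed(3)
  xs <- impute(y0, o0, u, um, ch$t0, ip, sigma_y = rep(0.3, N), stats = st,
               n_samples = 100)
  for (srep in 1:100) {
    expect_identical(xs[, , srep][o0 == 1], y0[o0 == 1])
  }
  # missing coordinates vary across samples
  miss_var <- apply(xs, c(1, 2), var)
  expect_true(all(miss_var[o0 == 0] > 0))
  # fully observed row is reproduced exactly with zero variance
  o1 <- matrix(1, 8, N)
  set.seed(4)
  x1 <- impute(y0, o1, u, um, ch$t0, ip, rep(0.3, N), st, n_samples = 5)
  expect_true(all(apply(x1, c(1, 2), var) == 0))
  expect_equal(x1[, , 1], y0)
  expect_error(impute(y0, o0, u, um, ch$t0, ip, rep(0.3, N), st, n_samples = 0),
               "n_samples")
})

test_that("baseline generation is seed-reproducible and sized correctly", {
  N <- 3
  ip <- imp_pars(N = N, seed = 7)
  ch <- toy_cohort(n = 5, N = N, seed = 3)
  st <- population_stats(ch)
  g0 <- generate_baseline(ch$u, ch$umask, ch$t0, ip, rep(0.2, N), st,
                          n_samples = 0)
  expect_equal(dim(g0), c(5, N, 0))
  set.seed(10)
  g1 <- generate_baseline(ch$u, ch$umask, ch$t0, ip, rep(0.2, N), st, n_samples = 2)
  set.seed(10)
  g2 <- generate_baseline(ch$u, ch$umask, ch$t0, ip, rep(0.2, N), st, n_samples = 2)
  expect_identical(g1, g2)
})
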
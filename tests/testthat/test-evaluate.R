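test_that("extreme orderings give concordance 1 and 0", {
  tau <- 0:10
  t0 <- rep(70, 3)
  a <- c(72, 75, 78); cc <- c(0, 0, 0)
  # survival ordered opposite to death ages: earliest death has lowest S
  S <- rbind(exp(-0.9 * tau), exp(-0.3 * tau), exp(-0.05 * tau))
  S[, 1] <- 1
  expect_equal(c_index_td(toy_pred(S, tau, t0, a, cc)), 1)
  expect_equal(c_index_td(toy_pred(S[3:1, ], tau, t0, a, cc)), 0)
  allc <- toy_pred(S, tau, t0, a, c = c(1, 1, 1))
  expect_true(is.na(c_index_td(allc)))
})

test_that("concordance and Brier match exhaustive enumeration on small sets", {
  for (seed in 1:12) {
    n <- sample(3:6, 1)
    pr <- rand_pred(n, seed)
    ci <- c_index_td(pr)
    or <- oracle_cindex(pr$S, pr$tau, pr$t0, pr$a, pr$c, pr$s, pr$source)
    if (is.na(or)) expect_true(is.na(ci)) else expect_equal(as.numeric(ci), or,
                                                            tolerance = 1e-12)
    tq <- quantile(pr$a, 0.5)
    expect_equal(brier_score(pr, tq),
                 oracle_brier(pr$S, pr$tau, pr$t0, pr$a, pr$c, pr$s, tq),
                 tolerance = 1e-12)
  }
})

test_that("same-source replica pairs are excluded from concordance", {
  tau <- 0:10; t0 <- rep(70, 4)
  S <- rbind(exp(-0.5 * tau), exp(-0.4 * tau), exp(-0.1 * tau), exp(-0.05 * tau))
  S[, 1] <- 1
  pr <- toy_pred(S, tau, t0, a = c(72, 74, 76, 78), c = rep(0, 4),
                 s = rep(0.5, 4), source = c("x", "x", "y", "y"))
  # pairs within x and within y are dropped; remaining pairs all concordant
  expect_equal(c_index_td(pr), 1)
})

test_that("the censoring Kaplan-Meier is the product-limit over censorings", {
  G <- censoring_km(c(2, 3, 5), c(0, 0, 0))
  expect_equal(G(c(1, 4, 10)), c(1, 1, 1))
  G2 <- censoring_km(c(4, 4, 4), c(1, 1, 1))
  expect_equal(G2(c(3.9, 4)), c(1, 0))
  # mixed toy: censorings at 2 and 6 (risk sets 5 and 2), deaths in between
  G3 <- censoring_km(c(1, 2, 3, 6, 7), c(0, 1, 0, 1, 0))
  expect_equal(G3(c(1, 2, 5, 6.5)), c(1, 1 - 1/4, 3/4, 3/4 * (1 - 1/2)))
  expect_error(censoring_km(numeric(), integer()), "empty")
})

test_that("Brier score has its closed-form values in degenerate cases", {
  tau <- 0:10; t0 <- rep(70, 4)
  a <- c(72, 75, 78, 80); cc <- rep(0, 4)
  # perfect step predictions: S jumps 1 -> 0 at the true death age
  S <- t(vapply(a, function(ai) as.numeric(70 + tau < ai), numeric(11)))
  pr <- toy_pred(S, tau, t0, a, cc)
  # evaluated on the curve grid, where the step is represented exactly
  for (t in c(71, 74, 79)) expect_equal(brier_score(pr, t), 0)
  # S = 1/2 with everyone alive at t: BS = 1/4
  pr2 <- toy_pred(matrix(0.5, 4, 11), tau, t0, a, cc)
  pr2$S[, 1] <- 0.5
  expect_equal(brier_score(pr2, 71), 0.25)
})

test_that("IBS is invariant to duplicating individuals with halved weights", {
  pr <- rand_pred(6, 99)
  ib1 <- integrated_brier(pr)
  pr2 <- toy_pred(rbind(pr$S, pr$S), pr$tau, c(pr$t0, pr$t0), c(pr$a, pr$a),
                  c(pr$c, pr$c), s = rep(pr$s / 2, 2),
                  source = c(pr$source, paste0("d", pr$source)))
  expect_equal(integrated_brier(pr2), ib1, tolerance = 1e-12)
  # perfect predictor: IBS = 0
  tau <- 0:10; t0 <- rep(70, 3); a <- c(72, 75, 78)
  S <- t(vapply(a, function(ai) as.numeric(70 + tau < ai), numeric(11)))
  expect_equal(integrated_brier(toy_pred(S, tau, t0, a, rep(0, 3))), 0)
})

test_that("D-calibration counts, statistic and censored mass behave correctly", {
  # exactly uniform deciles
  Su <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  d <- d_calibration(Su, rep(0, 100))
  expect_equal(d$counts, rep(10, 100 / 10))
  expect_equal(d$chi2, 0)
  expect_equal(d$p, 1)
  # the worked Pearson example: counts (20, 0, 10 x 8)
  Sx <- c(rep(0.05, 20), rep(0.25, 10), rep(0.35, 10), rep(0.45, 10),
          rep(0.55, 10), rep(0.65, 10), rep(0.75, 10), rep(0.85, 10),
          rep(0.95, 10))
  dx <- d_calibration(Sx, rep(0, 100))
  expect_equal(dx$counts, c(20, 0, rep(10, 8)))
  expect_equal(dx$chi2, 20)
  # a censored individual with S(a) = 0.35 spreads its mass over [0, 0.35]
  dc <- d_calibration(c(0.35, Su), c(1, rep(0, 100)), n_bins = 10)
  extra <- dc$counts - d$counts
  expect_equal(extra, c(0.1 / 0.35, 0.1 / 0.35, 0.1 / 0.35, 0.05 / 0.35,
                        rep(0, 6)))
  expect_equal(sum(dc$counts), 101)
  expect_error(d_calibration(runif(5), rep(0, 5), n_bins = 10), "fewer")
})

test_that("D-calibration p-values are uniform under perfect calibration", {
  # survival probabilities at death drawn from their own curves are uniform
  set.seed(13)
  ps <- replicate(60, d_calibration(runif(120), rep(0, 120))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.05)
})

test_that("the population discriminator separates only genuinely different cohorts", {
  set.seed(44)
  truth <- sample_ground_truth(3, 0.2)
  ch <- simulate_cohort(truth, 150, horizon = 6, dt = 0.1)
  st <- population_stats(ch)
  copy <- ch
  copy$id <- paste0("s", ch$id)
  set.seed(1)
  r1 <- population_discriminator(ch, copy, st)
  expect_lt(abs(r1$accuracy - 0.5), 3 * sqrt(0.25 / r1$n * 2))
  # fully observed cohort with one variable shifted far out of distribution
  truth0 <- truth; truth0$missing_rates <- rep(0, 3)
  set.seed(45)
  chf <- simulate_cohort(truth0, 150, horizon = 6, dt = 0.1)
  stf <- population_stats(chf)
  shifted <- chf
  shifted$id <- paste0("s", chf$id)
  for (m in seq_along(chf$id)) shifted$y[[m]][, 1] <- shifted$y[[m]][, 1] + 5
  set.seed(2)
  r2 <- population_discriminator(chf, shifted, stf)
  expect_gt(r2$accuracy, 0.9)
  set.seed(3); a1 <- population_discriminator(ch, copy, st)$accuracy
  set.seed(3); a2 <- population_discriminator(ch, copy, st)$accuracy
  expect_identical(a1, a2)
  few <- trajnet:::cohort_subset(ch, 1:2)
  expect_error(population_discriminator(ch, trajnet:::cohort_subset(copy, 1),
                                        st), "imbalance")
})

test_that("trajectory RMSE reduces to hand arithmetic and self-normalizes", {
  # mean-zero schema so raw = z * sd
  schema <- fit_schema(data.frame(v = c(-2, -1, 1, 2)), FALSE)
  sd1 <- schema$sd[1]
  tau <- c(0, 1, 2)
  # observed follow-up z-values +1 and -1; predictions off by +1 and +3 raw
  tm <- array(0, c(2, 3, 1))
  tm[1, 3, 1] <- 1 + 1 / sd1
  tm[2, 3, 1] <- -1 + 3 / sd1
  pred <- list(tau = tau, t0 = c(70, 70), traj_mean = tm)
  ch <- new_cohort(
    id = c("a", "b"), t0 = c(70, 70),
    times = list(c(70, 72), c(70, 72)),
    y = list(matrix(c(0, 1), 2, 1), matrix(c(0, -1), 2, 1)),
    o = list(matrix(1, 2, 1), matrix(1, 2, 1)),
    u = matrix(0, 2, 2), umask = matrix(1, 2, 2),
    a = c(72, 72), c = c(1L, 1L)
  )
  r <- traj_rmse(pred, ch, schema, variable = 1, min_years = 1)
  expect_equal(r, sqrt((1^2 + 3^2) / 2), tolerance = 1e-10)
  # an exact-prediction model scores 0
  pred0 <- pred
  pred0$traj_mean[1, 3, 1] <- 1
  pred0$traj_mean[2, 3, 1] <- -1
  expect_equal(traj_rmse(pred0, ch, schema, 1, min_years = 1), 0)
  # the matched-mean predictor scores exactly 1 against itself
  st <- population_stats(ch)
  predm <- pred
  predm$traj_mean[, , 1] <- st$global_mu[1]
  rr <- traj_rmse(predm, ch, schema, 1, min_years = 1, stats = st)
  expect_equal(rr, 1, tolerance = 1e-10)
})
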
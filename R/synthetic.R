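# Ground-truth cohort simulator.
#
# Generates cohorts with the statistical structure the model assumes: latent
# health states follow a linear-network SDE with mean-reverting self-dynamics
# (a known parametric stand-in for the learned per-variable nets, so that
# network recovery can be scored against truth), mortality follows a
# log-linear hazard in (x, age), observations add measurement noise, and
# missingness/censoring emulate survey cohorts: irregular ~2-year visits,
# block missingness for nurse-wave variables, and heavy mortality censoring.

#' Sample a ground-truth parameter set for the cohort simulator
#'
#' @param n_vars number of health variables N.
#' @param sparsity fraction of the N(N-1) off-diagonal interaction slots that
#'   are nonzero.
#' @param w_range magnitude range of nonzero interaction weights (signs are
#'   random).
#' @param hazard_vars how many variables carry a direct hazard coefficient.
#' @return an object of class `ground_truth`: interaction matrix `W` (zero
#'   diagonal), mean-reversion `rate` and `eq`, diffusion `sigma_x`,
#'   measurement noise `measurement_sd`, log-linear hazard coefficients
#'   (`h0` baseline log-hazard, `h_age` per-year age slope, `h_x` per-variable
#'   coefficients), per-variable `missing_rates`, `visit_gap_mean`, and
#'   `baseline_loading` (single-factor loading inducing the cross-sectional
#'   correlation between baseline health variables that real cohorts show;
#'   pairwise baseline correlation is its square).
#' @export
sample_ground_truth <- function(n_vars, sparsity, w_range = c(0.2, 0.5),
                                hazard_vars = 2) {
  if (sparsity < 0 || sparsity > 1) stop("sparsity must lie in [0, 1]")
  N <- n_vars
  W <- matrix(0, N, N)
  off <- which(row(W) != col(W))
  n_edges <- ceiling(sparsity * N * (N - 1) - 1e-9)
  if (n_edges > 0) {
    sel <- sample(off, n_edges)
    W[sel] <- sample(c(-1, 1), n_edges, replace = TRUE) *
      stats::runif(n_edges, w_range[1], w_range[2])
  }
  structure(
    list(
      W = W,
      rate = stats::runif(N, 0.25, 0.5),
      eq = rep(0, N),
      sigma_x = stats::runif(N, 0.12, 0.2),
      measurement_sd = stats::runif(N, 0.15, 0.3),
      h0 = log(0.01), h_age = 0.03,
      h_x = c(rep(0.3, min(hazard_vars, N)), rep(0, max(0, N - hazard_vars))),
      missing_rates = rep(0.3, N),
      visit_gap_mean = 2,
      baseline_loading = 0.6
    ),
    class = "ground_truth"
  )
}

# true drift: W x + diag mean reversion (x: n x N)
truth_drift <- function(x, truth) {
  x %*% t(truth$W) - sweep(sweep(x, 2L, truth$eq, "-"), 2L, truth$rate, "*")
}

truth_hazard <- function(x, t, truth) {
  exp(truth$h0 + truth$h_age * (t - 70) + as.vector(x %*% truth$h_x))
}

#' Simulate a synthetic cohort from known ground truth
#'
#' Latent states start from unit-variance baselines correlated through a
#' single common factor (loading `baseline_loading`) and evolve
#' by Euler-Maruyama integration of the network SDE; death is drawn each step
#' with per-step survival probability `exp(-lambda * dt)`; visits occur at
#' roughly `visit_gap_mean`-year intervals until death or end of follow-up;
#' observations add Gaussian measurement noise and entry-wise missingness.
#' Individuals dying before end of follow-up are uncensored at the simulated
#' death age; everyone else is censored at their last visit.
#'
#' @param truth a [sample_ground_truth()] object.
#' @param M number of individuals.
#' @param horizon follow-up length in years.
#' @param dt integration step (years); must be at most 0.5.
#' @param t0_range baseline-age range (years).
#' @return a `cohort`; the true interaction matrix is in
#'   `attr(, "truth")`.
#' @export
simulate_cohort <- function(truth, M, horizon = 10, dt = 0.1,
                            t0_range = c(65, 85)) {
  if (dt > 0.5) stop("dt must be at most 0.5")
  N <- length(truth$rate)
  t0 <- stats::runif(M, t0_range[1], t0_range[2])
  u_sex <- stats::rbinom(M, 1, 0.5)
  u2 <- stats::rnorm(M)
  U <- cbind(u_sex, u2)
  umask <- matrix(1, M, 2)
  n_steps <- ceiling(horizon / dt)
  lam <- truth$baseline_loading %||% 0
  f_common <- stats::rnorm(M)
  x <- lam * matrix(f_common, M, N) +
    sqrt(1 - lam^2) * matrix(stats::rnorm(M * N), M, N)
  # visit schedule per individual
  times <- lapply(seq_len(M), function(m) {
    gaps <- pmax(0.5, stats::rnorm(ceiling(horizon / truth$visit_gap_mean) + 1,
                                   truth$visit_gap_mean, 0.3))
    tt <- t0[m] + c(0, cumsum(gaps))
    tt[tt <= t0[m] + horizon + 1e-9]
  })
  # record latent state at each visit via nearest-step capture
  visit_steps <- lapply(seq_len(M), function(m) round((times[[m]] - t0[m]) / dt))
  xs <- lapply(seq_len(M), function(m) matrix(NA_real_, length(times[[m]]), N))
  death <- rep(NA_real_, M)
  alive <- rep(TRUE, M)
  for (m in seq_len(M)) if (0 %in% visit_steps[[m]]) {
    xs[[m]][which(visit_steps[[m]] == 0), ] <- x[m, ]
  }
  sqdt <- sqrt(dt)
  for (k in seq_len(n_steps)) {
    ages <- t0 + (k - 1) * dt
    drift <- truth_drift(x, truth)
    x_new <- x + drift * dt +
      matrix(stats::rnorm(M * N), M, N) * rep(truth$sigma_x, each = M) * sqdt
    if (any(!is.finite(x_new))) {
      stop("non-finite state during simulation; reduce dt or interaction weights")
    }
    lam <- truth_hazard(x, ages, truth)
    dies <- alive & (stats::runif(M) > exp(-lam * dt))
    death[dies] <- ages[dies] + dt / 2
    alive[dies] <- FALSE
    x <- x_new
    for (m in which(alive)) {
      hit <- which(visit_steps[[m]] == k)
      if (length(hit)) xs[[m]][hit, ] <- x[m, ]
    }
  }
  # assemble observations
  y <- o <- vector("list", M)
  a <- numeric(M); cflag <- integer(M)
  keep_times <- vector("list", M)
  for (m in seq_len(M)) {
    tt <- times[[m]]
    ok <- if (is.na(death[m])) rep(TRUE, length(tt)) else tt < death[m]
    ok[1] <- TRUE  # baseline always observed before any death
    tt <- tt[ok]
    X <- xs[[m]][ok, , drop = FALSE]
    Y <- X + matrix(stats::rnorm(length(tt) * N), length(tt), N) *
      rep(truth$measurement_sd, each = length(tt))
    O <- matrix(stats::rbinom(length(tt) * N, 1, 1 - rep(truth$missing_rates, each = length(tt))),
                length(tt), N)
    Y[O == 0] <- 0
    out <- finalize_outcomes(tt, death[m])
    keep_times[[m]] <- tt
    y[[m]] <- Y; o[[m]] <- O
    a[m] <- out$a; cflag[m] <- out$c
  }
  ch <- new_cohort(
    id = as.character(seq_len(M)), t0 = t0, times = keep_times, y = y, o = o,
    u = U, umask = umask, a = a, c = cflag
  )
  attr(ch, "truth") <- truth
  ch
}

#' Impose survey-style block missingness
#'
#' Nurse-evaluated variables are collected only every `nurse_period`-th wave
#' and additionally thinned at `nurse_rate`; self-reported variables are
#' thinned at `self_report_rate`.
#'
#' @param ch a `cohort`.
#' @param self_report_rate missingness rate added to self-report variables.
#' @param nurse_rate missingness rate added to nurse variables on nurse waves.
#' @param nurse_period collect nurse variables every this many waves.
#' @param nurse_vars indices of nurse-evaluated variables.
#' @return the thinned `cohort`.
#' @export
block_missingness <- function(ch, self_report_rate, nurse_rate, nurse_period = 2,
                              nurse_vars = integer()) {
  if (self_report_rate < 0 || self_report_rate > 1 ||
      nurse_rate < 0 || nurse_rate > 1) {
    stop("missingness rates must lie in [0, 1]")
  }
  N <- n_vars(ch)
  self_vars <- setdiff(seq_len(N), nurse_vars)
  for (m in seq_along(ch$id)) {
    O <- ch$o[[m]]
    K1 <- nrow(O)
    wave <- seq_len(K1)
    if (length(nurse_vars)) {
      off_wave <- (wave - 1) %% nurse_period != 0
      O[off_wave, nurse_vars] <- 0
      on_rows <- which(!off_wave)
      if (length(on_rows) && nurse_rate > 0) {
        thin <- matrix(stats::rbinom(length(on_rows) * length(nurse_vars), 1, 1 - nurse_rate),
                       length(on_rows), length(nurse_vars))
        O[on_rows, nurse_vars] <- O[on_rows, nurse_vars, drop = FALSE] * thin
      }
    }
    if (length(self_vars) && self_report_rate > 0) {
      thin <- matrix(stats::rbinom(K1 * length(self_vars), 1, 1 - self_report_rate),
                     K1, length(self_vars))
      O[, self_vars] <- O[, self_vars, drop = FALSE] * thin
    }
    ch$y[[m]][O == 0] <- 0
    ch$o[[m]] <- O
  }
  ch
}
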
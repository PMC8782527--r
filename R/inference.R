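# Variational objective and training.
#
# The per-individual objective combines (i) the masked Gaussian likelihood of
# observed health values at visit times, (ii) the survival likelihood with a
# dead-window penalty past the death age, (iii) the trajectory-space penalty
# forcing the posterior SDE toward the prior network dynamics, and (iv) KL
# terms: Laplace posteriors on interaction weights against Laplace(0, 0.05)
# priors, Gamma posteriors on measurement noise against Gamma(1, 25000), and
# the Gaussian-latent KL corrected by the flow log-determinant.

#' Masked Gaussian observation log-likelihood
#'
#' Sum over observed entries and visits of `log N(y | x, sigma_y)`.
#'
#' @param y matrix of observations (visits x variables).
#' @param o binary observation mask.
#' @param x matrix of model states at the visit times.
#' @param sigma_y per-variable measurement noise scale (> 0).
#' @return scalar log-likelihood.
#' @export
obs_loglik <- function(y, o, x, sigma_y) {
  if (any(sigma_y <= 0)) stop("sigma_y must be positive")
  y <- as.matrix(y); o <- as.matrix(o); x <- as.matrix(x)
  sy <- matrix(rep(sigma_y, each = nrow(y)), nrow(y), ncol(y))
  ll <- -0.5 * log(2 * pi) - log(sy) - 0.5 * ((y - x) / sy)^2
  sum(ll[o == 1])
}

#' Survival log-likelihood along a survival curve
#'
#' Uncensored: `log lambda(a) + log S(a) + int_a^{a+window} log(1 - S) dt`;
#' censored: `int_{t0}^{a} log S dt`. Integrals use the trapezoid rule on the
#' curve's grid; `S` is clamped to `[1e-6, 1 - 1e-6]` where logs would
#' diverge.
#'
#' @param curve a [survival_curve()] object.
#' @param a event age (death or last known alive).
#' @param censored 1 = censored, 0 = death observed.
#' @param window years past the death age over which being dead is rewarded.
#' @return scalar log-likelihood contribution.
#' @export
survival_loglik <- function(curve, a, censored, window = 5) {
  tms <- curve$times
  S_alive <- pmax(curve$S, 1e-6)        # guards log S
  S_dead <- pmin(curve$S, 1 - 1e-6)     # guards log(1 - S)
  ka <- which.min(abs(tms - a))
  trap_int <- function(vals, idx) {
    if (length(idx) < 2) return(0)
    sum(diff(tms[idx]) * (vals[idx[-length(idx)]] + vals[idx[-1]]) / 2)
  }
  if (censored == 1) {
    trap_int(log(S_alive), seq_len(ka))
  } else {
    ke <- which(tms <= a + window)
    ke <- ke[ke >= ka]
    log(max(curve$lambda[ka], 1e-12)) + log(S_alive[ka]) +
      trap_int(log(1 - S_dead), ke)
  }
}

#' Trajectory-space penalty between posterior and prior drift
#'
#' `-1/2 int || (W x - W_bar x - g) / sigma_x ||^2 dt` along a sampled path
#' (trapezoid rule), averaging over paths if a list is given. This is the
#' KL-derived term forcing the posterior SDE toward the network dynamics.
#'
#' @param path T+1 x N state matrix on the grid (or list of such matrices).
#' @param times grid ages.
#' @param W sampled interaction matrix.
#' @param W_bar posterior-mean interaction matrix.
#' @param g T+1 x N matrix of posterior-correction drift values along the
#'   path (or list).
#' @param sigma_x T+1 x N matrix (or list) of diffusion scales along the path.
#' @return scalar penalty (always <= 0).
#' @export
path_penalty <- function(path, times, W, W_bar, g, sigma_x) {
  one <- function(X, G, Sg) {
    if (any(Sg == 0)) stop("sigma_x must be nonzero along the path")
    mism <- X %*% t(W - W_bar) - G
    v <- rowSums((mism / Sg)^2)
    n <- length(times)
    -0.5 * sum(diff(times) * (v[-n] + v[-1]) / 2)
  }
  if (is.list(path)) {
    mean(mapply(one, path, g, sigma_x))
  } else {
    one(path, g, sigma_x)
  }
}

#' Closed-form KL between Laplace posterior and Laplace prior
#'
#' `KL(Laplace(m, b) || Laplace(0, s)) = log(s/b) + (b e^{-|m|/b} + |m|)/s - 1`,
#' summed over all entries.
#'
#' @param m posterior locations.
#' @param b posterior scales (> 0).
#' @param prior_scale prior scale s.
#' @return scalar KL.
#' @export
kl_laplace <- function(m, b, prior_scale = 0.05) {
  if (any(b <= 0)) stop("Laplace scales must be positive")
  sum(log(prior_scale / b) + (b * exp(-abs(m) / b) + abs(m)) / prior_scale - 1)
}

#' Closed-form KL between Gamma posterior and Gamma prior
#'
#' @param alpha,beta posterior shape and rate (> 0).
#' @param prior length-2 prior `(shape, rate)`.
#' @return scalar KL summed over variables.
#' @export
kl_gamma <- function(alpha, beta, prior = c(1, 25000)) {
  if (any(alpha <= 0) || any(beta <= 0) || any(prior <= 0)) {
    stop("Gamma parameters must be positive")
  }
  a0 <- prior[1]; b0 <- prior[2]
  sum((alpha - a0) * digamma(alpha) - lgamma(alpha) + lgamma(a0) +
        a0 * (log(beta) - log(b0)) + alpha * (b0 - beta) / beta)
}

#' Latent KL with flow correction
#'
#' Gaussian-vs-standard-normal KL of the base distribution minus the summed
#' flow log-determinants (per individual, then summed).
#'
#' @param mu,sigma base distribution location/scale matrices (n x latent).
#' @param log_det n x 1 accumulated flow log-Jacobians.
#' @return scalar.
#' @export
kl_latent <- function(mu, sigma, log_det = 0) {
  if (any(sigma <= 0)) stop("sigma_z must be positive")
  0.5 * sum(mu^2 + sigma^2 - 1 - 2 * log(sigma)) - sum(log_det)
}

#' KL annealing schedule
#'
#' Two linear ramps: `beta_xz` (latent and trajectory KL terms) over
#' `config$anneal_xz`, and `beta_W` (parameter-prior KL terms) over
#' `config$anneal_W`.
#'
#' @param epoch training epoch (0-based).
#' @param config a [trajnet_config()].
#' @return named numeric vector `c(beta_xz, beta_W)`.
#' @export
anneal_schedule <- function(epoch, config) {
  ramp <- function(e, w) min(max((e - w[1]) / (w[2] - w[1]), 0), 1)
  c(beta_xz = ramp(epoch, config$anneal_xz), beta_W = ramp(epoch, config$anneal_W))
}

#' Training configuration
#'
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param lr ADAM learning rate.
#' @param plateau_factor learning-rate decay factor at validation plateaus.
#' @param plateau_patience epochs without improvement before decay.
#' @param anneal_xz epoch window of the latent/trajectory KL ramp.
#' @param anneal_W epoch window of the parameter-prior KL ramp.
#' @param dt integration step in years.
#' @param window dead-window length in years past the death age.
#' @param keep_prob per-entry keep probability of baseline corruption.
#' @param latent latent dimension of the imputer.
#' @param n_flows number of coupling layers.
#' @param horizon integration horizon in years (`NULL`: derived from data as
#'   max event-age offset plus the dead window).
#' @param lr_floor lowest learning rate of the warm-phase decay (the rate
#'   halves every `plateau_patience` epochs while the KL terms anneal).
#' @param lr_post learning rate restored when annealing completes (`NULL`:
#'   keep the decayed rate).
#' @param prior_scale Laplace prior scale for interaction weights.
#' @param noise_prior Gamma prior `(shape, scale)` for the measurement-noise
#'   scale; the default `(1, 25000)` is an effectively flat exponential over
#'   the plausible z-scored noise range.
#' @param seed RNG seed for the fit.
#' @param verbose print progress every this many epochs (0 = quiet).
#' @return list of class `trajnet_config`.
#' @export
trajnet_config <- function(epochs = 500, batch_size = 1000, lr = 1e-2,
                           plateau_factor = 0.5, plateau_patience = 40,
                           anneal_xz = c(0, 300), anneal_W = c(300, 500),
                           dt = 0.5, window = 5, keep_prob = 0.9, latent = 20,
                           n_flows = 3, horizon = NULL, lr_floor = 1e-3,
                           lr_post = 2e-3, prior_scale = 0.05,
                           noise_prior = c(1, 25000), seed = 1, verbose = 0) {
  stopifnot(batch_size > 0, lr > 0, dt > 0, keep_prob > 0, keep_prob <= 1,
            anneal_xz[2] > anneal_xz[1], anneal_W[2] > anneal_W[1])
  structure(as.list(environment()), class = "trajnet_config")
}
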
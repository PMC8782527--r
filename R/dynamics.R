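# SDE dynamics of the health state.
#
# Prior drift: dx_i = (sum_j W_ij x_j + f_i(x_i, t, u)) dt + sigma_x,i(x) dB_i
# Posterior drift adds a small correction network g (the variational family
# over trajectories is itself an SDE). Integration uses an explicit
# derivative-free strong order 1.0 stochastic Runge-Kutta scheme for diagonal
# noise with a fixed step.
#
# Age enters every network as the centred feature (t - 70)/10.

tfeat <- function(t) (t - 70) / 10

# age feature column: accepts scalar, vector, or a precomputed n x 1 matrix
tf_col <- function(t, n) {
  if (is.matrix(t)) return(t)
  tf <- tfeat(t)
  if (length(tf) == 1L) tf <- rep(tf, n)
  matrix(tf, ncol = 1L)
}

# Per-variable self-dynamics nets f_i(x_i, t, u): implemented as one
# block-diagonal computation so that variable i's hidden units see only x_i
# (plus the shared conditioning inputs t, u, umask), exactly equivalent to N
# separate networks with their own weights but far cheaper on the tape.
fblock_init <- function(N, B, hidden = 12, zero_out = TRUE) {
  H <- hidden * N
  Mx <- matrix(0, N, H)
  Mv <- matrix(0, H, N)
  for (i in seq_len(N)) {
    cols <- (i - 1) * hidden + seq_len(hidden)
    Mx[i, cols] <- 1
    Mv[cols, i] <- 1
  }
  s_in <- sqrt(2 / (2 + 2 * B + hidden))
  list(
    Wx = matrix(stats::rnorm(N * H, sd = s_in), N, H) * Mx,
    Wc = matrix(stats::rnorm((1 + 2 * B) * H, sd = s_in), 1 + 2 * B, H),
    b1 = rep(0, H),
    V = if (zero_out) matrix(0, H, N) else
      matrix(stats::rnorm(H * N, sd = sqrt(2 / (hidden + 1))), H, N) * Mv,
    b2 = rep(0, N),
    Mx = Mx, Mv = Mv
  )
}

drift_f <- function(x, t, u, umask, fp) {
  n <- nrow(advl(x))
  C <- cbind(tf_col(t, n), advl(u), advl(umask))
  H <- ad_elu(ad_addrow(ad_add(ad_matmul(x, ad_mul(fp$Wx, fp$Mx)),
                               ad_matmul(C, fp$Wc)), fp$b1))
  ad_addrow(ad_matmul(H, ad_mul(fp$V, fp$Mv)), fp$b2)
}

# posterior correction net; -> n x N
drift_g <- function(x, t, u, umask, gpars) {
  nn_mlp(ad_cbind(x, u, tf_col(t, nrow(advl(x))), umask), gpars)
}

# state-dependent diagonal diffusion, strictly positive; -> n x N
diffusion_sigma <- function(x, sigpars, floor = 0.01) {
  ad_add(ad_softplus(nn_mlp(x, sigpars)), floor)
}

#' Prior network drift
#'
#' Component i is `sum_j W_ij x_j + f_i(x_i, t, u)`: linear directed coupling
#' through the interaction matrix plus a per-variable nonlinear self-dynamics
#' network.
#'
#' @param x n x N state matrix.
#' @param t age (scalar or length-n vector, years).
#' @param u n x B background covariates.
#' @param umask n x B background missing mask.
#' @param W N x N interaction matrix (zero diagonal).
#' @param pars model parameter list containing `f` (per-variable nets).
#' @return n x N drift matrix.
#' @export
prior_drift <- function(x, t, u, umask, W, pars) {
  xv <- advl(x)
  if (ncol(xv) != nrow(advl(W))) stop("state/interaction-matrix shape mismatch")
  Wt <- if (is.ad(W)) ad_t(W) else t(W)
  ad_add(ad_matmul(x, Wt), drift_f(x, t, u, umask, pars$f))
}

# internal: x %*% t(W) where W may be a node (transpose handled by caller)
drift_linear <- function(x, Wt) ad_matmul(x, Wt)

#' Posterior drift
#'
#' The prior drift evaluated at the posterior-mean interaction matrix, plus
#' the small fully-connected correction network g that defines the
#' variational family over trajectories.
#'
#' @inheritParams prior_drift
#' @param W_bar posterior-mean interaction matrix.
#' @return n x N drift matrix.
#' @export
posterior_drift <- function(x, t, u, umask, W_bar, pars) {
  ad_add(prior_drift(x, t, u, umask, W_bar, pars),
         drift_g(x, t, u, umask, pars$g))
}

#' Integrate an SDE ensemble with a strong order 1.0 scheme
#'
#' Explicit stochastic Runge-Kutta step of strong order 1.0 for diagonal
#' noise: classical four-stage Runge-Kutta for the drift combined with the
#' derivative-free Milstein correction for the diffusion,
#' `x' = x + dt/6 (k1 + 2 k2 + 2 k3 + k4) + s dW +
#' (s(xsup) - s(x)) (dW^2 - dt) / (2 sqrt(dt))` with
#' `xsup = x + k1 dt + s sqrt(dt)`. In the zero-noise limit this reduces to
#' fourth-order Runge-Kutta; with multiplicative diagonal noise the Milstein
#' correction limits (and attains) strong order 1.0.
#'
#' @param x0 n x N matrix of initial states (one row per path).
#' @param t0 baseline ages (scalar or length n).
#' @param u,umask background covariates and mask (n x B).
#' @param pars parameter list (`f`, `g`, `sig`, and `W_bar`/`W` as used).
#' @param horizon integration length in years.
#' @param dt fixed step (years).
#' @param mode `"posterior"` (drift with correction g at the posterior mean
#'   `W_bar`) or `"prior"` (network drift at matrix `W`).
#' @param W interaction matrix to use; defaults to `pars$W_bar`.
#' @param dW optional list of pre-drawn n x N Brownian increments per step
#'   (for shared-path comparisons); drawn internally if `NULL`.
#' @param drift,diffusion optional closures `function(x, t)` overriding the
#'   model drift/diffusion (used by latent-space variants and tests).
#' @return list: `times` (absolute ages, length T+1 when t0 is scalar, else
#'   offsets), `xs` (list of n x N states per grid point), `dW` (increments).
#' @export
sde_integrate <- function(x0, t0, u = NULL, umask = NULL, pars = NULL,
                          horizon, dt, mode = c("posterior", "prior"),
                          W = NULL, dW = NULL, drift = NULL, diffusion = NULL) {
  mode <- match.arg(mode)
  n <- nrow(advl(x0)); N <- ncol(advl(x0))
  n_steps <- round(horizon / dt)
  if (is.null(drift)) {
    Wuse <- W %||% pars$W_bar
    Wt <- if (is.ad(Wuse)) ad_t(Wuse) else t(advl(Wuse))
    drift <- if (mode == "posterior") {
      function(x, t) ad_add(ad_add(ad_matmul(x, Wt), drift_f(x, t, u, umask, pars$f)),
                            drift_g(x, t, u, umask, pars$g))
    } else {
      function(x, t) ad_add(ad_matmul(x, Wt), drift_f(x, t, u, umask, pars$f))
    }
  }
  if (is.null(diffusion)) diffusion <- function(x, t) diffusion_sigma(x, pars$sig)
  xs <- vector("list", n_steps + 1L)
  xs[[1]] <- x0
  draws <- !is.null(dW)
  if (!draws) dW <- vector("list", n_steps)
  sqdt <- sqrt(dt)
  x <- x0
  for (k in seq_len(n_steps)) {
    tk <- t0 + (k - 1) * dt
    k1 <- drift(x, tk)
    k2 <- drift(ad_add(x, ad_mul(k1, dt / 2)), tk + dt / 2)
    k3 <- drift(ad_add(x, ad_mul(k2, dt / 2)), tk + dt / 2)
    k4 <- drift(ad_add(x, ad_mul(k3, dt)), tk + dt)
    s <- diffusion(x, tk)
    if (!draws) dW[[k]] <- matrix(stats::rnorm(n * N, sd = sqdt), n, N)
    xsup <- ad_add(ad_add(x, ad_mul(k1, dt)), ad_mul(s, sqdt))
    ssup <- diffusion(xsup, tk)
    corr <- ad_mul(ad_sub(ssup, s), (dW[[k]]^2 - dt) / (2 * sqdt))
    incr <- ad_mul(ad_add(ad_add(k1, k4), ad_mul(ad_add(k2, k3), 2)), dt / 6)
    x <- ad_add(ad_add(ad_add(x, incr), ad_mul(s, dW[[k]])), corr)
    xv <- advl(x)
    if (any(!is.finite(xv))) {
      stop("non-finite state at step ", k, " (path ",
           which(!is.finite(rowSums(xv)))[1], "); reduce dt or drift weights")
    }
    xs[[k + 1L]] <- x
  }
  list(times = if (length(t0) == 1L) t0 + dt * (0:n_steps) else dt * (0:n_steps),
       xs = xs, dW = dW)
}

#' Latent-space drift variant
#'
#' Full feed-forward drift on a latent state z (no interaction matrix), for
#' latent-space model variants with a tunable latent dimension. With
#' `summary_1d = TRUE` the background covariates are removed from the drift
#' input (they then enter only through the encoder), giving the 1D-summary
#' configuration.
#'
#' @param z n x L latent state.
#' @param t age (scalar or length-n).
#' @param u,umask background covariates and mask.
#' @param pars latent drift parameter list (an MLP from [latent_init()]).
#' @param summary_1d drop `u` from the drift input.
#' @return n x L drift matrix.
#' @export
latent_drift <- function(z, t, u, umask, pars, summary_1d = FALSE) {
  tf <- tfeat(t)
  if (length(tf) == 1L) tf <- rep(tf, nrow(advl(z)))
  inp <- if (summary_1d) ad_cbind(z, matrix(tf, ncol = 1L))
         else ad_cbind(z, u, matrix(tf, ncol = 1L), umask)
  nn_mlp(inp, pars)
}

#' Initialize latent drift parameters
#'
#' @param latent_dim latent dimension (1..30).
#' @param B number of background covariates.
#' @param hidden hidden layer width.
#' @param summary_1d whether the drift input omits `u`.
#' @param zero zero-initialize the output layer (zero drift at start).
#' @return MLP parameter list usable with [latent_drift()].
#' @export
latent_init <- function(latent_dim, B, hidden = 12, summary_1d = FALSE,
                        zero = FALSE) {
  n_in <- if (summary_1d) latent_dim + 1 else latent_dim + 2 * B + 1
  nn_mlp_init(n_in, hidden, latent_dim, zero_out = zero)
}
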
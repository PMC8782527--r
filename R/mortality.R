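# History-dependent mortality: a 2-layer GRU consumes the health trajectory
# along the integration grid and emits a nonnegative hazard at each grid
# point (exponential link). The initial hidden state is produced from the
# baseline state, background covariates and baseline age. Survival curves
# integrate the hazard with the trapezoid rule on the same grid.

hazard_init_params <- function(N, B, h1 = 25, h2 = 10) {
  list(
    H = nn_dense_init(N + 2 * B + 1, h1 + h2),
    gru1 = nn_gru_init(N + 1, h1),
    gru2 = nn_gru_init(h1, h2),
    head = nn_dense_init(h2, 1, zero = TRUE),
    n_h1 = h1, n_h2 = h2
  )
}

# advance the GRU along xs (list of n x N states); returns list of n x 1
# hazard columns, one per grid point
hazard_forward <- function(xs, t0, u, umask, hpars, dt = 0) {
  n <- nrow(advl(xs[[1]]))
  h1 <- hpars$n_h1; h2 <- hpars$n_h2
  h0 <- ad_tanh(ad_addrow(
    ad_matmul(ad_cbind(xs[[1]], u, umask, tf_col(t0, n)), hpars$H$W),
    hpars$H$b))
  hs1 <- ad_cols(h0, seq_len(h1))
  hs2 <- ad_cols(h0, h1 + seq_len(h2))
  lam <- raws <- vector("list", length(xs))
  for (k in seq_along(xs)) {
    inp <- ad_cbind(xs[[k]], tf_col(t0 + (k - 1) * dt, n))
    hs1 <- nn_gru_step(inp, hs1, hpars$gru1, h1)
    hs2 <- nn_gru_step(hs1, hs2, hpars$gru2, h2)
    raw <- ad_clamp(ad_addrow(ad_matmul(hs2, hpars$head$W), hpars$head$b), -18, 6)
    raws[[k]] <- raw
    lam[[k]] <- ad_exp(raw)
  }
  list(lam = lam, raw = raws)
}

#' Hazard path along a trajectory
#'
#' Initializes the recurrent hidden state from the baseline, then advances a
#' 2-layer GRU once per grid step consuming the health state, emitting a
#' nonnegative hazard (exponential link on the top hidden layer).
#'
#' @param trajectory T+1 x N matrix of health states on the grid, or the
#'   result of [sde_integrate()] for one path.
#' @param times grid ages (length T+1, constant spacing).
#' @param u,umask background covariates (length-B vectors) and mask.
#' @param hpars hazard parameters from `hazard_init_params()`.
#' @return numeric vector of hazards on the grid.
#' @export
hazard_path <- function(trajectory, times, u, umask, hpars) {
  if (is.list(trajectory)) {
    times <- trajectory$times
    trajectory <- do.call(rbind, lapply(trajectory$xs, function(m) advl(m)[1, ]))
  }
  T1 <- nrow(trajectory)
  if (length(times) != T1) stop("grid/trajectory length mismatch")
  xs <- lapply(seq_len(T1), function(k) trajectory[k, , drop = FALSE])
  dt <- if (T1 > 1) times[2] - times[1] else 0
  hz <- hazard_forward(xs, times[1], matrix(u, nrow = 1), matrix(umask, nrow = 1),
                       hpars, dt = dt)
  vapply(hz$lam, function(l) advl(l)[1, 1], numeric(1))
}

#' Survival curve from a hazard path
#'
#' `S(t) = exp(-int lambda)` with the integral computed by the trapezoid rule
#' on the grid; `S(t0) = 1`.
#'
#' @param lambda_path nonnegative hazard values on the grid.
#' @param times grid ages.
#' @return object of class `survival_curve`: list with `times`, `S`, `lambda`.
#' @export
survival_curve <- function(lambda_path, times) {
  if (any(lambda_path < 0)) stop("hazard must be nonnegative")
  stopifnot(length(lambda_path) == length(times))
  n <- length(times)
  cum <- numeric(n)
  if (n > 1) {
    dt <- diff(times)
    cum[-1] <- cumsum(dt * (lambda_path[-n] + lambda_path[-1]) / 2)
  }
  structure(list(times = times, S = exp(-cum), lambda = lambda_path),
            class = "survival_curve")
}

#' Sample a death age along a hazard path
#'
#' Per grid step the individual survives with probability
#' `exp(-lambda(t) dt)`; the first failing step returns its midpoint as the
#' death age. Surviving every step returns `NA` (censored at horizon).
#'
#' @param lambda_path hazard on the grid (the last value is unused).
#' @param times grid ages.
#' @return death age, or `NA` if alive at the end of the grid.
#' @export
sample_death <- function(lambda_path, times) {
  n <- length(times)
  if (n < 2) return(NA_real_)
  dt <- diff(times)
  p_die <- 1 - exp(-lambda_path[-n] * dt)
  u <- stats::runif(n - 1)
  hit <- which(u < p_die)
  if (length(hit) == 0L) return(NA_real_)
  k <- hit[1]
  times[k] + dt[k] / 2
}
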
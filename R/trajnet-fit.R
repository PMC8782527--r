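#' Fit the joint network-SDE model of health trajectories and survival
#'
#' Fits, by stochastic variational inference, a joint model in which N health
#' variables evolve by a stochastic differential equation whose drift couples
#' variables linearly through a directed interaction matrix W plus
#' per-variable nonlinear self-dynamics, mortality follows a GRU hazard fed
#' by the trajectory, and missing baselines are imputed by a normalizing-flow
#' VAE trained jointly. Interaction weights carry independent Laplace
#' posteriors (location `W_bar`, scale `b`) against Laplace(0, 0.05) priors;
#' measurement-noise scales carry Gamma posteriors against Gamma(1, 25000)
#' priors; all other parameters are point-estimated.
#'
#' @param cohort training `cohort` on the transformed (z-scored) scale.
#' @param val optional validation `cohort`; if `NULL` a 20% tail of
#'   `cohort` is held out.
#' @param config a [trajnet_config()].
#' @param replicate replicate individuals over all possible baseline waves
#'   (with weights summing to one per source) before training.
#' @return An object of class `trajnet` with components `par` (all fitted
#'   parameters), `posterior` (`W_bar`, `b`, `alpha`, `beta`, `sigma_y`),
#'   `config`, `stats` (population statistics used for filling), `history`
#'   (per-epoch losses) and `best_epoch`.
#' @seealso [predict.trajnet()], [simulate.trajnet()], [prune_network()]
#' @export
trajnet <- function(cohort, val = NULL, config = trajnet_config(),
                    replicate = TRUE) {
  if (is.null(val)) {
    set.seed(config$seed)
    M <- length(cohort$id)
    hold <- sample.int(M, max(1L, round(0.2 * M)))
    val <- cohort_subset(cohort, hold)
    cohort <- cohort_subset(cohort, setdiff(seq_len(M), hold))
  }
  if (replicate) {
    cohort <- replicate_baselines(cohort)
    val <- replicate_baselines(val)
  }
  res <- tn_train(cohort, val, config, full_model = TRUE)
  par <- res$par
  N <- n_vars(cohort)
  alpha <- exp(as.vector(par$log_alpha))
  beta <- exp(as.vector(par$log_beta))
  b <- exp(par$log_b); diag(b) <- NA_real_
  W_bar <- par$W_bar; diag(W_bar) <- 0
  structure(
    list(par = par, config = config, stats = res$stats,
         history = res$history, best_epoch = res$best_epoch,
         diverged = res$diverged, N = N, B = n_background(cohort),
         horizon = res$prep$horizon,
         posterior = list(W_bar = W_bar, b = b, alpha = alpha, beta = beta,
                          sigma_y = alpha / beta)),
    class = "trajnet"
  )
}

#' @export
print.trajnet <- function(x, ...) {
  cat("Joint network-SDE model:", x$N, "health variables,", x$B,
      "background covariates\n")
  if (nrow(x$history)) {
    cat("  epochs:", nrow(x$history), " best validation epoch:", x$best_epoch,
        " final val loss:", round(utils::tail(x$history$val, 1), 4), "\n")
  }
  pr <- prune_network(x)
  cat("  robust edges at 99% credible level:", sum(pr$pruned_mask), "of",
      x$N * (x$N - 1), "\n")
  invisible(x)
}

#' @export
summary.trajnet <- function(object, level = 0.99, ...) {
  pr <- prune_network(object, level = level)
  edges <- export_edges(object, level = level)
  out <- list(N = object$N, level = level,
              n_robust = sum(pr$pruned_mask),
              sigma_y = object$posterior$sigma_y,
              edges = edges[order(-abs(edges$mean)), ],
              history = object$history)
  class(out) <- "summary.trajnet"
  out
}

#' @export
print.summary.trajnet <- function(x, ...) {
  cat("Robust directed interactions (", x$level * 100, "% credible level): ",
      x$n_robust, "\n", sep = "")
  top <- utils::head(x$edges[x$edges$robust, ], 10)
  if (nrow(top)) print(top, row.names = FALSE)
  cat("measurement noise sd (posterior mean):",
      paste(round(x$sigma_y, 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.trajnet <- function(object, ...) object$posterior$W_bar

#' Predict trajectories and survival for new individuals
#'
#' Multiply imputes each baseline, integrates the posterior SDE forward and
#' runs the hazard GRU along each sampled path. Survival curves average
#' `exp(-int lambda)` over paths; trajectory summaries are across-path means
#' and standard deviations.
#'
#' @param object a fitted `trajnet`.
#' @param newdata a `cohort` on the transformed scale.
#' @param n_samples number of sampled paths per individual.
#' @param horizon prediction horizon in years (default: the fitted horizon).
#' @param dt grid step (default: the training step).
#' @param ... unused.
#' @return object of class `trajnet_pred`: list with `tau` (grid offsets from
#'   baseline), `t0`, `traj_mean`, `traj_sd` (n x T x N arrays), `S`
#'   (n x T survival curves), `lambda` (n x T mean hazard), and the
#'   individual outcome columns copied from `newdata` (`a`, `c`, `s`).
#' @export
predict.trajnet <- function(object, newdata, n_samples = 20, horizon = NULL,
                            dt = NULL, ...) {
  cfg <- object$config
  dt <- dt %||% cfg$dt
  horizon <- horizon %||% object$horizon
  ch <- newdata
  n <- length(ch$id); N <- object$N
  T1 <- ceiling(horizon / dt + 1e-9) + 1L
  bm <- baseline_matrix(ch)
  sy <- object$posterior$sigma_y
  par <- object$par
  Ctr <- tn_cumtrapz_matrix(T1, dt)
  mean_t <- m2_t <- array(0, c(n, T1, N))
  Ssum <- matrix(0, n, T1)
  Lsum <- matrix(0, n, T1)
  for (srep in seq_len(n_samples)) {
    x0 <- impute(bm$y0, bm$o0, ch$u, ch$umask, ch$t0, par$imp, sy,
                 object$stats, sex = ch$u[, 1], n_samples = 1)[, , 1]
    sim <- sde_integrate(x0, ch$t0, ch$u, ch$umask, par,
                         horizon = (T1 - 1) * dt, dt = dt, mode = "posterior")
    xs <- sim$xs
    hz <- hazard_forward(xs, ch$t0, ch$u, ch$umask, par$haz, dt = dt)
    Lmat <- do.call(cbind, lapply(hz$lam, advl))
    Ssum <- Ssum + exp(-(Lmat %*% Ctr))
    Lsum <- Lsum + Lmat
    for (k in seq_len(T1)) {
      xv <- advl(xs[[k]])
      mean_t[, k, ] <- mean_t[, k, ] + xv
      m2_t[, k, ] <- m2_t[, k, ] + xv^2
    }
  }
  mean_t <- mean_t / n_samples
  sd_t <- sqrt(pmax(m2_t / n_samples - mean_t^2, 0))
  structure(
    list(tau = dt * (seq_len(T1) - 1L), t0 = ch$t0, traj_mean = mean_t,
         traj_sd = sd_t, S = Ssum / n_samples, lambda = Lsum / n_samples,
         a = ch$a, c = ch$c, s = ch$s, id = ch$id, source = ch$source),
    class = "trajnet_pred"
  )
}

#' Evaluate predicted survival at arbitrary ages
#'
#' Linear interpolation of each individual's predicted survival curve;
#' constant extrapolation beyond the grid.
#'
#' @param pred a `trajnet_pred`.
#' @param ages evaluation ages (recycled against individuals if scalar).
#' @return vector of survival probabilities, one per individual.
#' @export
survival_at <- function(pred, ages) {
  n <- nrow(pred$S)
  if (length(ages) == 1L) ages <- rep(ages, n)
  vapply(seq_len(n), function(m) {
    stats::approx(pred$t0[m] + pred$tau, pred$S[m, ], xout = ages[m],
                  yleft = 1, yright = pred$S[m, ncol(pred$S)])$y
  }, numeric(1))
}

#' Simulate a synthetic population from the fitted generative model
#'
#' Samples synthetic baselines from the latent prior given each individual's
#' background information, integrates the generative network SDE
#' (posterior-mean interaction matrix, no posterior correction), samples
#' death ages along the hazard path, observes the state at the visit
#' schedule of `newdata` with measurement noise, and applies `newdata`'s
#' missingness pattern.
#'
#' @param object a fitted `trajnet`.
#' @param nsim number of synthetic populations.
#' @param seed optional RNG seed.
#' @param newdata a `cohort` supplying background covariates, baseline ages,
#'   visit schedules and observation masks.
#' @param ... unused.
#' @return a synthetic `cohort` (list of them if `nsim > 1`).
#' @export
simulate.trajnet <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i) tn_simulate_one(object, newdata))
  if (nsim == 1) out[[1]] else out
}

tn_simulate_one <- function(object, ch) {
  par <- object$par
  n <- length(ch$id); N <- object$N
  sy <- object$posterior$sigma_y
  dt <- object$config$dt
  max_tau <- max(vapply(seq_len(n), function(m) max(ch$times[[m]]) - ch$t0[m],
                        numeric(1)))
  T1 <- ceiling(max_tau / dt + 1e-9) + 1L
  x0 <- generate_baseline(ch$u, ch$umask, ch$t0, par$imp, sy, object$stats,
                          sex = ch$u[, 1], n_samples = 1)[, , 1]
  sim <- sde_integrate(x0, ch$t0, ch$u, ch$umask, par, horizon = (T1 - 1) * dt,
                       dt = dt, mode = "prior", W = par$W_bar)
  hz <- hazard_forward(sim$xs, ch$t0, ch$u, ch$umask, par$haz, dt = dt)
  Lmat <- do.call(cbind, lapply(hz$lam, advl))
  X <- lapply(sim$xs, advl)
  times <- y <- o <- vector("list", n)
  a <- numeric(n); cflag <- integer(n)
  for (m in seq_len(n)) {
    death <- sample_death(Lmat[m, ], ch$t0[m] + dt * (seq_len(T1) - 1L))
    tt <- ch$times[[m]]
    if (!is.na(death)) {
      keep <- tt < death | seq_along(tt) == 1L
      tt <- tt[keep]
    } else {
      keep <- rep(TRUE, length(tt))
    }
    ks <- pmin(pmax(round((tt - ch$t0[m]) / dt), 0L) + 1L, T1)
    Xm <- t(vapply(ks, function(k) X[[k]][m, ], numeric(N)))
    Y <- Xm + matrix(stats::rnorm(length(tt) * N), length(tt), N) *
      rep(sy, each = length(tt))
    O <- ch$o[[m]][keep, , drop = FALSE]
    Y[O == 0] <- 0
    fo <- finalize_outcomes(tt, death)
    times[[m]] <- tt; y[[m]] <- Y; o[[m]] <- O
    a[m] <- fo$a; cflag[m] <- fo$c
  }
  new_cohort(id = paste0("syn", seq_len(n)), t0 = ch$t0, times = times, y = y,
             o = o, u = ch$u, umask = ch$umask, a = a, c = cflag)
}

#' Residuals at observed follow-up visits
#'
#' Observed minus predicted mean trajectory, on the transformed scale, at
#' every observed (individual, visit, variable) triple.
#'
#' @param object a fitted `trajnet`.
#' @param newdata a `cohort`.
#' @param pred optional precomputed [predict.trajnet()] result.
#' @param ... passed to `predict.trajnet`.
#' @return data frame with columns `id`, `age`, `variable`, `observed`,
#'   `predicted`, `residual`.
#' @export
residuals.trajnet <- function(object, newdata, pred = NULL, ...) {
  pred <- pred %||% predict.trajnet(object, newdata, ...)
  dt <- pred$tau[2] - pred$tau[1]
  out <- list()
  for (m in seq_along(newdata$id)) {
    tt <- newdata$times[[m]]
    ks <- pmin(round((tt - newdata$t0[m]) / dt) + 1L, length(pred$tau))
    for (j in seq_along(tt)) {
      obs <- which(newdata$o[[m]][j, ] == 1)
      if (!length(obs)) next
      out[[length(out) + 1L]] <- data.frame(
        id = newdata$id[m], age = tt[j], variable = obs,
        observed = newdata$y[[m]][j, obs],
        predicted = pred$traj_mean[m, ks[j], obs]
      )
    }
  }
  res <- do.call(rbind, out)
  res$residual <- res$observed - res$predicted
  res
}

#' Plot the inferred interaction network
#'
#' Heatmap of the posterior-mean interaction matrix with rows/columns in the
#' hierarchical-clustering leaf order of the robust-network dissimilarity.
#'
#' @param x a fitted `trajnet`.
#' @param level credible level for pruning.
#' @param ... passed to [graphics::image()].
#' @export
plot.trajnet <- function(x, level = 0.99, ...) {
  pr <- prune_network(x, level = level)
  W <- pr$W_robust
  ord <- tryCatch(cluster_network(W)$order, error = function(e) seq_len(nrow(W)))
  Wo <- W[ord, ord, drop = FALSE]
  graphics::image(seq_len(nrow(Wo)), seq_len(ncol(Wo)), t(Wo),
                  xlab = "source variable", ylab = "target variable",
                  main = "robust interaction weights", ...)
  invisible(x)
}

#' Fit the baseline imputer alone
#'
#' Trains encoder, flows and decoder (plus the measurement-noise posterior)
#' on baseline reconstruction with masking corruption only, without the
#' dynamics or mortality components. Useful for imputation benchmarks and as
#' a quick-look model.
#'
#' @inheritParams trajnet
#' @return object of class `trajnet_imputer` with `par`, `stats`, `config`,
#'   `history`.
#' @export
fit_imputer <- function(cohort, val = NULL, config = trajnet_config(),
                        replicate = FALSE) {
  if (is.null(val)) {
    set.seed(config$seed)
    M <- length(cohort$id)
    hold <- sample.int(M, max(1L, round(0.2 * M)))
    val <- cohort_subset(cohort, hold)
    cohort <- cohort_subset(cohort, setdiff(seq_len(M), hold))
  }
  if (replicate) {
    cohort <- replicate_baselines(cohort)
    val <- replicate_baselines(val)
  }
  res <- tn_train(cohort, val, config, full_model = FALSE)
  structure(
    list(par = res$par, stats = res$stats, config = config,
         history = res$history,
         sigma_y = as.vector(exp(res$par$log_alpha - res$par$log_beta))),
    class = "trajnet_imputer"
  )
}

#' Impute missing baseline entries of a cohort
#'
#' @param fit a `trajnet_imputer` or `trajnet`.
#' @param cohort a `cohort`.
#' @param n_samples imputation draws.
#' @return array n x N x n_samples from [impute()].
#' @export
impute_cohort <- function(fit, cohort, n_samples = 10) {
  bm <- baseline_matrix(cohort)
  sy <- if (inherits(fit, "trajnet")) fit$posterior$sigma_y else fit$sigma_y
  impute(bm$y0, bm$o0, cohort$u, cohort$umask, cohort$t0, fit$par$imp, sy,
         fit$stats, sex = cohort$u[, 1], n_samples = n_samples)
}
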
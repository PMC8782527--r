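# Linear comparison models: elastic-net Cox proportional hazards with a
# Breslow baseline hazard, per-variable elastic-net linear trajectory
# models, and chained-equations random-forest imputation for their inputs.
#
# The hazard is log-linear in (baseline age, baseline health state,
# background covariates); the time axis is years from baseline, with
# baseline age entering as a covariate. Elastic-net penalties use the
# (alpha, l1_ratio) parameterization `alpha * (l1 |b|_1 + (1-l1)/2 |b|_2^2)`;
# defaults are the printed random-search optima.

#' Fit an elastic-net Cox model with Breslow baseline hazard
#'
#' @param y0 M x N baseline health matrix (complete; impute first).
#' @param u M x B background covariates.
#' @param t0 baseline ages.
#' @param a event ages; `censored` flags (1 = censored).
#' @param penalty overall penalty strength alpha (0 gives an unpenalized
#'   fit via [survival::coxph()]).
#' @param l1_ratio elastic-net mixing in [0, 1].
#' @return object of class `coxnet_breslow`: coefficients `beta` (order:
#'   t0, y-columns, u-columns), Breslow cumulative baseline hazard step
#'   function (`breslow_time`, `breslow_hazard` on the years-from-baseline
#'   axis), and the penalty settings.
#' @export
cox_fit <- function(y0, u, t0, a, censored, penalty = 0.00016,
                    l1_ratio = 0.15613) {
  time <- a - t0
  event <- 1 - censored
  if (sum(event) == 0) stop("no events in training data")
  X <- cbind(t0 = t0, as.matrix(y0), as.matrix(u))
  time <- pmax(time, 1e-8)
  if (penalty > 0) {
    fit <- glmnet::glmnet(X, survival::Surv(time, event), family = "cox",
                          alpha = l1_ratio, lambda = penalty,
                          standardize = FALSE)
    beta <- as.vector(stats::coef(fit))
  } else {
    df <- data.frame(time = time, event = event, X)
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(colnames(df)[-(1:2)], collapse = "+")))
    beta <- unname(stats::coef(survival::coxph(fml, data = df, ties = "breslow")))
  }
  lp <- as.vector(X %*% beta)
  # Breslow estimator on the years-from-baseline axis
  ord <- order(time)
  ts <- time[ord]; ev <- event[ord]; elp <- exp(lp)[ord]
  ut <- unique(ts[ev == 1])
  dLam <- vapply(ut, function(tj) {
    sum(ev == 1 & ts == tj) / sum(elp[ts >= tj])
  }, numeric(1))
  structure(
    list(beta = beta, names = colnames(X), breslow_time = ut,
         breslow_hazard = cumsum(dLam), penalty = penalty,
         l1_ratio = l1_ratio),
    class = "coxnet_breslow"
  )
}

#' Survival curve from a fitted Cox model
#'
#' `S(t) = exp(-Lambda0(t - t0) * exp(beta . x))` with the Breslow step
#' cumulative baseline hazard; times before the first event give S = 1.
#'
#' @param model a [cox_fit()] result.
#' @param y0,u,t0 covariates as in [cox_fit()].
#' @param t evaluation ages (absolute, years).
#' @return matrix of survival probabilities, individuals x times.
#' @export
cox_survival <- function(model, y0, u, t0, t) {
  X <- cbind(t0 = t0, as.matrix(y0), as.matrix(u))
  lp <- as.vector(X %*% model$beta)
  Lam0 <- function(tau) {
    vapply(tau, function(x) {
      idx <- which(model$breslow_time <= x + 1e-12)
      if (!length(idx)) 0 else model$breslow_hazard[max(idx)]
    }, numeric(1))
  }
  out <- matrix(NA_real_, length(lp), length(t))
  for (m in seq_along(lp)) {
    out[m, ] <- exp(-Lam0(t - t0[m]) * exp(lp[m]))
  }
  out
}

#' Fit per-variable elastic-net linear trajectory models
#'
#' Model: `y_i(t) = y0_i + slope_i(y0, u, t0) * (t - t0)` with
#' `slope_i = b00 + b0 t0 + b1 . y0 + b2 . u` fit by elastic net on all
#' observed follow-up values of variable i (the slope intercept is included
#' as a penalized column).
#'
#' @param cohort a `cohort` with complete baselines (`y0_fill` overrides).
#' @param y0_fill optional M x N complete baseline matrix (e.g. from
#'   [mice_rf_impute()]).
#' @param penalty,l1_ratio elastic-net settings (printed optima as defaults).
#' @return object of class `linear_traj`: list of per-variable coefficient
#'   vectors (NA where a variable was never observed at two times).
#' @export
linear_traj_fit <- function(cohort, y0_fill = NULL, penalty = 0.40423,
                            l1_ratio = 0.55942) {
  N <- n_vars(cohort)
  bm <- baseline_matrix(cohort)
  y0 <- y0_fill %||% bm$y0
  coefs <- vector("list", N)
  for (i in seq_len(N)) {
    Z <- list(); r <- list()
    for (m in seq_along(cohort$id)) {
      tt <- cohort$times[[m]]
      if (length(tt) < 2) next
      sel <- which(cohort$o[[m]][, i] == 1 & seq_along(tt) > 1)
      if (!length(sel)) next
      dtau <- tt[sel] - cohort$t0[m]
      base <- c(1, cohort$t0[m], y0[m, ], cohort$u[m, ])
      Z[[length(Z) + 1L]] <- outer(dtau, base)
      r[[length(r) + 1L]] <- cohort$y[[m]][sel, i] - y0[m, i]
    }
    if (length(Z) < 2) {
      coefs[i] <- list(NULL)
      next
    }
    Zm <- do.call(rbind, Z); rv <- unlist(r)
    if (all(abs(rv) < 1e-12)) {
      # no observed change: every penalized solution is the zero slope
      coefs[[i]] <- rep(0, ncol(Zm))
      next
    }
    fit <- glmnet::glmnet(Zm, rv, alpha = l1_ratio, lambda = penalty,
                          intercept = FALSE, standardize = FALSE)
    coefs[[i]] <- as.vector(stats::coef(fit))[-1]
  }
  structure(list(coefs = coefs, N = N), class = "linear_traj")
}

#' Predict health trajectories from the linear model
#'
#' @param model a [linear_traj_fit()] result.
#' @param y0 complete baseline matrix (M x N).
#' @param u background covariates; `t0` baseline ages.
#' @param t evaluation ages.
#' @return array M x length(t) x N; variables without a fitted model are NA.
#' @export
linear_traj_predict <- function(model, y0, u, t0, t) {
  M <- nrow(y0); N <- model$N
  out <- array(NA_real_, c(M, length(t), N))
  for (i in seq_len(N)) {
    if (is.null(model$coefs[[i]])) next
    for (m in seq_len(M)) {
      base <- c(1, t0[m], y0[m, ], u[m, ])
      slope <- sum(model$coefs[[i]] * base)
      out[m, , i] <- y0[m, i] + slope * (t - t0[m])
    }
  }
  out
}

#' Chained-equations imputation with random forests
#'
#' Iteratively models each variable with missing entries as a random forest
#' on the current completion of the other variables, replacing missing
#' entries with the forest's mean prediction; repeated for `n_iter` sweeps
#' after a mean-fill initialization. Thin orchestration over standard
#' learners in support of the linear baselines.
#'
#' @param table data frame or matrix with `NA`s; fully numeric.
#' @param n_trees trees per forest.
#' @param max_depth maximum tree depth.
#' @param n_iter chained sweeps.
#' @param seed RNG seed for the forests.
#' @return completed matrix.
#' @export
mice_rf_impute <- function(table, n_trees = 40, max_depth = 10, n_iter = 5,
                           seed = 1) {
  X <- as.matrix(table)
  miss <- is.na(X)
  if (!any(miss)) return(X)
  if (any(colSums(!miss) == 0)) stop("column fully missing; cannot impute")
  set.seed(seed)
  for (j in seq_len(ncol(X))) {
    if (any(miss[, j])) X[miss[, j], j] <- mean(X[!miss[, j], j])
  }
  cols <- which(colSums(miss) > 0)
  for (it in seq_len(n_iter)) {
    for (j in cols) {
      obs <- !miss[, j]
      df <- data.frame(y = X[obs, j], X[obs, -j, drop = FALSE])
      fit <- ranger::ranger(y ~ ., data = df, num.trees = n_trees,
                            max.depth = max_depth, seed = seed + it * 131 + j,
                            num.threads = 1)
      newd <- data.frame(X[miss[, j], -j, drop = FALSE])
      names(newd) <- names(df)[-1]
      X[miss[, j], j] <- stats::predict(fit, data = newd)$predictions
    }
  }
  X
}
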
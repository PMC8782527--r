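# Evaluation metrics: trajectory RMSE on the raw scale, time-dependent
# concordance, IPCW Brier score, D-calibration, and the two-sample
# population-realism classifier.

#' Weighted trajectory RMSE on the raw scale
#'
#' Root of the sample-weighted mean squared error between predicted and
#' observed values after inverting the variable transform (un-z-scoring and
#' exponentiating log-scaled variables). The relative variant divides by the
#' RMSE of the sex- and age-matched population-mean predictor.
#'
#' @param pred a `trajnet_pred`.
#' @param cohort the `cohort` holding the observed follow-up visits.
#' @param schema the `var_schema` used on this cohort.
#' @param variable variable index.
#' @param min_years only visits at least this many years past baseline count.
#' @param stats optional [population_stats()]; if given, the result is the
#'   relative RMSE (model / matched-mean predictor).
#' @return scalar RMSE (or relative RMSE); `NA` with a message attribute if
#'   no observed entries qualify.
#' @export
traj_rmse <- function(pred, cohort, schema, variable, min_years = 0,
                      stats = NULL) {
  dt <- pred$tau[2] - pred$tau[1]
  T1 <- length(pred$tau)
  e_model <- e_base <- w <- numeric(0)
  for (m in seq_along(cohort$id)) {
    tt <- cohort$times[[m]]
    sel <- which(tt - cohort$t0[m] >= min_years & cohort$o[[m]][, variable] == 1)
    if (!length(sel)) next
    ks <- pmin(round((tt[sel] - cohort$t0[m]) / dt) + 1L, T1)
    zpred <- pred$traj_mean[m, ks, variable]
    zobs <- cohort$y[[m]][sel, variable]
    raw_pred <- inv_col(zpred, schema, variable)
    raw_obs <- inv_col(zobs, schema, variable)
    e_model <- c(e_model, (raw_pred - raw_obs)^2)
    w <- c(w, rep(cohort$s[m], length(sel)))
    if (!is.null(stats)) {
      ps <- pop_lookup(stats, cohort$u[m, 1], rep(tt[sel], 1))
      raw_base <- inv_col(ps$mu[, variable], schema, variable)
      e_base <- c(e_base, (raw_base - raw_obs)^2)
    }
  }
  if (!length(e_model)) {
    return(structure(NA_real_, message = "no observed entries for this variable"))
  }
  r <- sqrt(sum(w * e_model) / sum(w))
  if (is.null(stats)) return(r)
  r / sqrt(sum(w * e_base) / sum(w))
}

inv_col <- function(z, schema, j) {
  v <- z * schema$sd[j] + schema$mean[j]
  if (schema$log_flags[j]) exp(v) else v
}

#' Time-dependent concordance index
#'
#' Weighted proportion of comparable pairs -- the earlier event uncensored --
#' in which the model assigns the earlier-dying individual the lower survival
#' probability at that death age:
#' `Pr(S1(a1) < S2(a1) | a1 < a2, c1 = 0)`. Pairs with equal event ages are
#' excluded; ties in predicted survival count as discordant (strict
#' inequality). Pairs of replicas of the same source individual are excluded.
#'
#' @param pred a `trajnet_pred`, or any list with fields `S` (n x T survival
#'   matrix), `tau` (grid offsets), `t0`, `a`, `c`, and optionally `s`
#'   (weights) and `source`.
#' @param age_range optional baseline-age interval `c(lo, hi)`: only pairs
#'   whose baseline ages both fall inside are used (stratified evaluation).
#' @return concordance in [0, 1]; `NA` with a message if no comparable pairs.
#' @export
c_index_td <- function(pred, age_range = NULL) {
  n <- length(pred$a)
  s <- pred$s %||% rep(1, n)
  src <- pred$source %||% as.character(seq_len(n))
  keep <- rep(TRUE, n)
  if (!is.null(age_range)) keep <- pred$t0 >= age_range[1] & pred$t0 <= age_range[2]
  ev_idx <- which(keep & pred$c == 0)
  if (!length(ev_idx)) return(structure(NA_real_, message = "no comparable pairs"))
  # survival of everyone at each uncensored event age
  Sat <- function(t) {
    vapply(seq_len(n), function(m) {
      stats::approx(pred$t0[m] + pred$tau, pred$S[m, ], xout = t, yleft = 1,
                    yright = pred$S[m, ncol(pred$S)])$y
    }, numeric(1))
  }
  num <- den <- 0
  for (m1 in ev_idx) {
    a1 <- pred$a[m1]
    cand <- which(keep & pred$a > a1 & src != src[m1])
    if (!length(cand)) next
    Sv <- Sat(a1)
    wpair <- s[m1] * s[cand]
    den <- den + sum(wpair)
    num <- num + sum(wpair * (Sv[m1] < Sv[cand]))
  }
  if (den == 0) return(structure(NA_real_, message = "no comparable pairs"))
  num / den
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimator treating censorings as events and deaths as
#' censorings; used for inverse-probability-of-censoring weighting.
#'
#' @param a event ages.
#' @param censored censor flags (1 = censored).
#' @return function `G(t, minus = FALSE)` evaluating the step function
#'   (right-continuous; `minus = TRUE` gives the left limit).
#' @export
censoring_km <- function(a, censored) {
  if (!length(a)) stop("empty input")
  fit <- survival::survfit(survival::Surv(a, censored == 1) ~ 1)
  tms <- fit$time; Sv <- fit$surv
  function(t, minus = FALSE) {
    vapply(t, function(ti) {
      idx <- if (minus) which(tms < ti - 1e-12) else which(tms <= ti + 1e-12)
      if (!length(idx)) 1 else Sv[max(idx)]
    }, numeric(1))
  }
}

#' IPCW Brier score at a time point
#'
#' `BS(t) = (1/W) sum_m s_m [ 1(a_m <= t, c_m = 0) S_m(t)^2 / G(a_m^-) +
#' 1(a_m > t) (1 - S_m(t))^2 / G(t) ]` with G the Kaplan-Meier censoring
#' survival. Individuals whose weight denominator vanishes are excluded.
#'
#' @param pred a `trajnet_pred` (or compatible list, see [c_index_td()]).
#' @param t evaluation age.
#' @param G optional precomputed [censoring_km()] function.
#' @return Brier score at `t`.
#' @export
brier_score <- function(pred, t, G = NULL) {
  n <- length(pred$a)
  s <- pred$s %||% rep(1, n)
  G <- G %||% censoring_km(pred$a, pred$c)
  St <- vapply(seq_len(n), function(m) {
    stats::approx(pred$t0[m] + pred$tau, pred$S[m, ], xout = t, yleft = 1,
                  yright = pred$S[m, ncol(pred$S)])$y
  }, numeric(1))
  dead <- pred$a <= t & pred$c == 0
  alive <- pred$a > t
  contrib <- numeric(n)
  ok <- rep(TRUE, n)
  Gm <- G(pred$a, minus = TRUE)
  Gt <- G(t)
  for (m in seq_len(n)) {
    if (dead[m]) {
      if (Gm[m] <= 0) { ok[m] <- FALSE; next }
      contrib[m] <- St[m]^2 / Gm[m]
    } else if (alive[m]) {
      if (Gt <= 0) { ok[m] <- FALSE; next }
      contrib[m] <- (1 - St[m])^2 / Gt
    }
  }
  sum(s[ok] * contrib[ok]) / sum(s[ok])
}

#' Integrated Brier score
#'
#' Trapezoid integral of `BS(t)` over the observed death-age range, divided
#' by the range length.
#'
#' @param pred a `trajnet_pred` (or compatible list).
#' @return scalar IBS.
#' @export
integrated_brier <- function(pred) {
  G <- censoring_km(pred$a, pred$c)
  ts <- sort(unique(pred$a[pred$c == 0]))
  if (length(ts) < 2) stop("need at least two distinct death ages")
  bs <- vapply(ts, function(t) brier_score(pred, t, G), numeric(1))
  sum(diff(ts) * (bs[-length(bs)] + bs[-1]) / 2) / (max(ts) - min(ts))
}

#' D-calibration of survival predictions
#'
#' Bins each uncensored individual by the predicted survival probability at
#' the death age; for a calibrated model these probability-integral
#' transforms are uniform. Censored individuals redistribute their unit mass
#' uniformly over the quantile interval `[0, S(a)]`. A Pearson chi-squared
#' statistic against the uniform distribution is reported with
#' `n_bins - 1` degrees of freedom.
#'
#' @param S_event predicted survival probability at each individual's event
#'   age.
#' @param censored censor flags (1 = censored).
#' @param n_bins number of probability bins (default 10).
#' @return list: `counts` (possibly fractional, length `n_bins`, bins from
#'   [0, 1/n_bins) upward), `chi2`, `p`.
#' @export
d_calibration <- function(S_event, censored, n_bins = 10) {
  n <- length(S_event)
  if (n < n_bins) stop("fewer individuals than bins")
  edges <- seq(0, 1, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  for (m in seq_len(n)) {
    Sm <- min(max(S_event[m], 0), 1)
    if (censored[m] == 0) {
      b <- min(n_bins, floor(Sm * n_bins) + 1L)
      counts[b] <- counts[b] + 1
    } else {
      if (Sm < 1e-12) {
        counts[1] <- counts[1] + 1
        next
      }
      for (b in seq_len(n_bins)) {
        lo <- edges[b]; hi <- edges[b + 1]
        if (lo >= Sm) break
        counts[b] <- counts[b] + (min(hi, Sm) - lo) / Sm
      }
    }
  }
  E <- n / n_bins
  chi2 <- sum((counts - E)^2 / E)
  list(counts = counts, chi2 = chi2,
       p = stats::pchisq(chi2, df = n_bins - 1, lower.tail = FALSE))
}

#' Two-sample population-realism classifier
#'
#' Trains a linear logistic classifier to distinguish observed from
#' synthetic individuals from rows `(age, y_t, u)` pooled over visits, with
#' missing values filled by the sex- and age-matched population mean (the
#' synthetic cohort is expected to already carry the observed missingness
#' pattern). Indistinguishable populations give held-out accuracy near 0.5.
#'
#' @param real,synthetic `cohort` objects on the same schema.
#' @param stats [population_stats()] from the real training data, used for
#'   mean-filling.
#' @param holdout fraction of rows held out for the reported accuracy.
#' @param strata_breaks optional years-from-baseline breaks for stratified
#'   accuracies.
#' @return list: `accuracy` (held-out overall), `by_stratum` (data frame),
#'   `n` rows used.
#' @export
population_discriminator <- function(real, synthetic, stats, holdout = 0.5,
                                     strata_breaks = NULL) {
  rows <- function(ch, label) {
    out <- list()
    for (m in seq_along(ch$id)) {
      tt <- ch$times[[m]]
      Y <- ch$y[[m]]; O <- ch$o[[m]]
      ps <- pop_lookup(stats, rep(ch$u[m, 1], length(tt)), tt)
      Yf <- ifelse(O == 1, Y, ps$mu)
      out[[m]] <- data.frame(label = label, age = tt, tau = tt - ch$t0[m], Yf,
                             t(replicate(length(tt), ch$u[m, ])))
    }
    do.call(rbind, out)
  }
  df <- rbind(rows(real, 0L), rows(synthetic, 1L))
  bal <- mean(df$label)
  if (bal < 0.05 || bal > 0.95) stop("class imbalance exceeds 95/5")
  idx <- sample.int(nrow(df))
  n_te <- round(holdout * nrow(df))
  te <- idx[seq_len(n_te)]; tr <- idx[-seq_len(n_te)]
  feats <- setdiff(names(df), c("label", "tau"))
  fml <- stats::as.formula(paste("label ~", paste(feats, collapse = "+")))
  fit <- suppressWarnings(stats::glm(fml, data = df[tr, ], family = stats::binomial()))
  p <- stats::predict(fit, newdata = df[te, ], type = "response")
  acc <- mean((p > 0.5) == (df$label[te] == 1))
  by_stratum <- NULL
  if (!is.null(strata_breaks)) {
    g <- cut(df$tau[te], strata_breaks, include.lowest = TRUE)
    by_stratum <- data.frame(
      stratum = levels(g),
      accuracy = as.vector(tapply((p > 0.5) == (df$label[te] == 1), g, mean))
    )
  }
  list(accuracy = acc, by_stratum = by_stratum, n = nrow(df))
}
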
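# Cohort container and the preprocessing/augmentation rules around it.
#
# A `cohort` holds, per individual: baseline age t0, visit ages (years,
# strictly increasing, baseline first), a (K+1) x N health matrix on the
# transformed scale with a binary observation mask (1 = observed), background
# covariates u with their own missing mask, the survival outcome (event age a,
# censor flag c: 1 = censored), and a sample weight s used when individuals
# are replicated across alternative baselines.

#' Construct a cohort object
#'
#' @param id vector of individual identifiers.
#' @param t0 numeric vector of baseline ages (years).
#' @param times list of numeric vectors of visit ages (baseline first,
#'   strictly increasing).
#' @param y list of (K+1) x N health matrices on the transformed scale.
#' @param o list of matching binary observation masks (1 = observed).
#' @param u M x B matrix of background covariates (missing entries 0-filled).
#' @param umask M x B binary missing mask for `u`.
#' @param a numeric vector of event ages: death age (uncensored) or last known
#'   alive age (censored).
#' @param c integer vector of censoring flags, 1 = censored.
#' @param s numeric vector of sample weights in (0, 1].
#' @param source identifiers of the source individual for replicas
#'   (defaults to `id`).
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(id, t0, times, y, o, u, umask, a, c, s = rep(1, length(id)),
                       source = id) {
  u <- as.matrix(u); umask <- as.matrix(umask)
  ch <- structure(
    list(id = id, t0 = t0, times = times, y = y, o = o, u = u, umask = umask,
         a = a, c = as.integer(c), s = s, source = source),
    class = "cohort"
  )
  validate_cohort(ch)
  ch
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", length(x$id), "individuals (",
      length(unique(x$source)), "sources ),",
      ncol(x$y[[1]]), "health variables,", ncol(x$u), "background covariates\n")
  cat("  deaths:", sum(x$c == 0), " censored:", sum(x$c == 1),
      " mean visits:", round(mean(lengths(x$times)), 2), "\n")
  invisible(x)
}

#' Check cohort invariants
#'
#' Event age at or after baseline, binary masks, strictly increasing visit
#' ages, weights in (0, 1], and replica weights summing to one per source
#' individual.
#'
#' @param ch a `cohort`.
#' @return `ch`, invisibly; errors if an invariant is violated.
#' @export
validate_cohort <- function(ch) {
  M <- length(ch$id)
  stopifnot(
    length(ch$t0) == M, length(ch$times) == M, length(ch$y) == M,
    length(ch$o) == M, nrow(ch$u) == M, length(ch$a) == M,
    length(ch$c) == M, length(ch$s) == M
  )
  if (any(ch$a < ch$t0 - 1e-9)) stop("event age precedes baseline age")
  if (!all(ch$c %in% c(0L, 1L))) stop("censor flags must be 0/1")
  if (any(ch$s <= 0 | ch$s > 1)) stop("sample weights must lie in (0, 1]")
  for (m in seq_len(M)) {
    tm <- ch$times[[m]]
    if (length(tm) > 1 && any(diff(tm) <= 0)) stop("visit ages must be strictly increasing")
    if (abs(tm[1] - ch$t0[m]) > 1e-9) stop("first visit age must equal t0")
    if (!all(ch$o[[m]] %in% c(0, 1))) stop("observation mask entries must be 0/1")
    if (any(dim(ch$y[[m]]) != dim(ch$o[[m]]))) stop("y/o dimension mismatch")
  }
  ws <- tapply(ch$s, ch$source, sum)
  if (any(abs(ws - 1) > 1e-6)) stop("replica weights must sum to 1 per source individual")
  invisible(ch)
}

n_vars <- function(ch) ncol(ch$y[[1]])
n_background <- function(ch) ncol(ch$u)

# baseline (first-visit) health matrix and mask, M x N
baseline_matrix <- function(ch) {
  N <- n_vars(ch)
  Y <- vapply(ch$y, function(m) m[1, ], numeric(N))
  O <- vapply(ch$o, function(m) m[1, ], numeric(N))
  if (N == 1L) {
    list(y0 = matrix(Y, ncol = 1), o0 = matrix(O, ncol = 1))
  } else {
    list(y0 = t(Y), o0 = t(O))
  }
}

# subset individuals by index
cohort_subset <- function(ch, idx) {
  structure(
    list(id = ch$id[idx], t0 = ch$t0[idx], times = ch$times[idx], y = ch$y[idx],
         o = ch$o[idx], u = ch$u[idx, , drop = FALSE],
         umask = ch$umask[idx, , drop = FALSE], a = ch$a[idx], c = ch$c[idx],
         s = ch$s[idx], source = ch$source[idx]),
    class = "cohort"
  )
}

#' Finalize the survival outcome of one individual
#'
#' No recorded death means censoring at the last observed age; a recorded
#' death gives an uncensored outcome at the death age.
#'
#' @param visit_ages numeric vector of visit ages.
#' @param death_age death age in years, or `NA` if no death was recorded.
#' @return list with event age `a` and censor flag `c` (1 = censored).
#' @export
finalize_outcomes <- function(visit_ages, death_age = NA) {
  stopifnot(length(visit_ages) >= 1)
  if (is.na(death_age)) {
    list(a = max(visit_ages), c = 1L)
  } else {
    if (death_age < visit_ages[1]) stop("death age precedes baseline age")
    list(a = death_age, c = 0L)
  }
}

#' Carry a slowly-varying variable forward (and backward) across visits
#'
#' Last observation carried forward; a missing leading stretch is filled
#' backward from the first available measurement. Used for variables such as
#' height that are effectively constant over follow-up.
#'
#' @param values numeric vector over visits.
#' @param mask binary observation vector (1 = observed).
#' @return list with filled `values` and updated `mask`.
#' @export
carry_forward <- function(values, mask) {
  obs <- which(mask == 1)
  if (length(obs) == 0L) return(list(values = values, mask = mask))
  v <- values
  last <- NA
  for (k in seq_along(v)) {
    if (mask[k] == 1) last <- v[k] else if (!is.na(last)) v[k] <- last
  }
  first <- v[obs[1]]
  if (obs[1] > 1) v[seq_len(obs[1] - 1)] <- first
  list(values = v, mask = rep(1, length(values)))
}

#' Replicate individuals across all possible baseline waves
#'
#' Each visit wave becomes an alternative baseline, yielding one replica per
#' wave; every replica of a source individual gets weight 1/(number of
#' replicas) so each source contributes unit total weight to the likelihood.
#' Test-split replicas additionally require at least one follow-up visit.
#'
#' @param ch a `cohort`.
#' @param test logical; if `TRUE`, drop replicas without a follow-up visit.
#' @return the replicated `cohort`; replica ids are `<id>#<wave>`.
#' @export
replicate_baselines <- function(ch, test = FALSE) {
  out <- list()
  for (m in seq_along(ch$id)) {
    tm <- ch$times[[m]]
    K1 <- length(tm)
    waves <- seq_len(K1)
    if (test) waves <- waves[waves < K1]  # need >= 1 follow-up visit
    if (length(waves) == 0L) waves <- 1L
    w <- 1 / length(waves)
    for (k in waves) {
      out[[length(out) + 1L]] <- list(
        id = paste0(ch$id[m], "#", k), source = ch$id[m],
        t0 = tm[k], times = tm[k:K1],
        y = ch$y[[m]][k:K1, , drop = FALSE], o = ch$o[[m]][k:K1, , drop = FALSE],
        u = ch$u[m, ], umask = ch$umask[m, ], a = ch$a[m], c = ch$c[m], s = w
      )
    }
  }
  new_cohort(
    id = vapply(out, `[[`, character(1), "id"),
    t0 = vapply(out, `[[`, numeric(1), "t0"),
    times = lapply(out, `[[`, "times"),
    y = lapply(out, `[[`, "y"),
    o = lapply(out, `[[`, "o"),
    u = do.call(rbind, lapply(out, `[[`, "u")),
    umask = do.call(rbind, lapply(out, `[[`, "umask")),
    a = vapply(out, `[[`, numeric(1), "a"),
    c = vapply(out, `[[`, integer(1), "c"),
    s = vapply(out, `[[`, numeric(1), "s"),
    source = vapply(out, `[[`, character(1), "source")
  )
}

#' Sex- and age-stratified population statistics
#'
#' Per-variable means and standard deviations on the transformed scale,
#' stratified by sex and 5-year age bins, pooled over all visits. Used to
#' fill missing entries with plausible population draws before encoding.
#'
#' @param ch a `cohort`.
#' @param sex optional numeric vector (one per individual) defining the sex
#'   stratum; `NULL` pools everyone.
#' @param age_width age bin width in years.
#' @return an object of class `pop_stats`.
#' @export
population_stats <- function(ch, sex = NULL, age_width = 5) {
  N <- n_vars(ch)
  ages <- unlist(ch$times)
  reps <- lengths(ch$times)
  sexv <- if (is.null(sex)) rep(0, length(ch$id)) else sex
  sex_long <- rep(sexv, reps)
  Y <- do.call(rbind, ch$y)
  O <- do.call(rbind, ch$o)
  bin <- floor(ages / age_width)
  key <- paste(sex_long, bin)
  strata <- unique(key)
  mu <- sd_ <- matrix(NA_real_, length(strata), N, dimnames = list(strata, NULL))
  for (s in strata) {
    rows <- key == s
    for (j in seq_len(N)) {
      v <- Y[rows, j][O[rows, j] == 1]
      if (length(v) >= 2) {
        mu[s, j] <- mean(v)
        sd_[s, j] <- stats::sd(v)
      }
    }
  }
  gmu <- gsd <- numeric(N)
  for (j in seq_len(N)) {
    v <- Y[, j][O[, j] == 1]
    gmu[j] <- if (length(v)) mean(v) else 0
    gsd[j] <- if (length(v) >= 2) stats::sd(v) else 1
  }
  sd_[!is.na(sd_) & sd_ <= 0] <- NA_real_
  structure(
    list(mu = mu, sd = sd_, global_mu = gmu, global_sd = gsd, age_width = age_width),
    class = "pop_stats"
  )
}

# look up stratified stats for rows (sex, t0); returns list(mu, sd) matrices;
# silently falls back to global statistics unless warn = TRUE
pop_lookup <- function(stats, sex, t0, warn = FALSE) {
  N <- length(stats$global_mu)
  n <- length(t0)
  key <- paste(sex, floor(t0 / stats$age_width))
  mu <- matrix(rep(stats$global_mu, each = n), n, N)
  sd_ <- matrix(rep(stats$global_sd, each = n), n, N)
  hit <- key %in% rownames(stats$mu)
  if (any(hit)) {
    m <- stats$mu[key[hit], , drop = FALSE]
    s <- stats$sd[key[hit], , drop = FALSE]
    keep <- !is.na(m) & !is.na(s)
    mu[hit, ][keep] <- m[keep]
    sd_[hit, ][keep] <- s[keep]
  }
  if (!all(hit) && warn) {
    warning("population stratum without statistics; falling back to global statistics")
  }
  list(mu = mu, sd = sd_)
}

#' Corrupt a baseline state for self-supervised training
#'
#' Each observed baseline entry is kept with probability `keep_prob`; dropped
#' and genuinely missing entries are temporarily filled with Gaussian draws
#' from the matching sex/age stratum of the population statistics. The
#' returned keep indicator marks entries that survived corruption, enabling
#' reconstruction of the artificially masked values as a self-supervision
#' signal.
#'
#' @param y0 M x N baseline matrix (transformed scale).
#' @param o0 M x N binary observation mask.
#' @param keep_prob per-entry keep probability (the corruption rate is
#'   `1 - keep_prob`).
#' @param stats a [population_stats()] object.
#' @param t0 baseline ages (length M).
#' @param sex optional sex stratum vector (length M).
#' @return list: `y_tilde` (filled, corrupted baseline), `keep` (binary keep
#'   indicator matrix).
#' @export
corrupt_baseline <- function(y0, o0, keep_prob, stats, t0, sex = NULL) {
  y0 <- as.matrix(y0); o0 <- as.matrix(o0)
  n <- nrow(y0); N <- ncol(y0)
  sexv <- if (is.null(sex)) rep(0, n) else sex
  keep <- matrix(stats::rbinom(n * N, 1L, keep_prob), n, N)
  eff <- keep * o0
  ps <- pop_lookup(stats, sexv, t0, warn = TRUE)
  fill <- ps$mu + ps$sd * matrix(stats::rnorm(n * N), n, N)
  y_t <- y0
  y_t[is.na(y_t)] <- 0
  y_tilde <- eff * y_t + (1 - eff) * fill
  list(y_tilde = y_tilde, keep = keep)
}

#' Split a cohort into train / validation / test sets
#'
#' Individual-level disjoint split. Training and validation drop individuals
#' with fewer than `min_train` observed baseline variables; the full test set
#' is kept for population-level comparisons, with a `prediction` attribute
#' marking individuals with at least `min_test` observed baseline variables
#' (the prediction subset).
#'
#' @param ch a `cohort` (one row per source individual; split before
#'   replication so replicas share their source's assignment).
#' @param fractions length-3 numeric summing to 1.
#' @param min_train minimum observed baseline variables for train/validation.
#' @param min_test minimum observed baseline variables for the test
#'   prediction subset.
#' @return list of cohorts `train`, `val`, `test`; `attr(test, "prediction")`
#'   is the logical prediction-subset indicator.
#' @export
split_cohort <- function(ch, fractions = c(0.66, 0.17, 0.17),
                         min_train = 6, min_test = 10) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  M <- length(ch$id)
  idx <- sample.int(M)
  n_tr <- round(fractions[1] * M)
  n_va <- round(fractions[2] * M)
  tr <- idx[seq_len(n_tr)]
  va <- idx[n_tr + seq_len(n_va)]
  te <- idx[-seq_len(n_tr + n_va)]
  nobs0 <- vapply(ch$o, function(o) sum(o[1, ]), numeric(1))
  train <- cohort_subset(ch, tr[nobs0[tr] >= min_train])
  val <- cohort_subset(ch, va[nobs0[va] >= min_train])
  test <- cohort_subset(ch, te)
  attr(test, "prediction") <- nobs0[te] >= min_test
  list(train = train, val = val, test = test)
}

#' Write / read a cohort as two delimited text tables
#'
#' `individuals.tsv` holds one row per individual (id, t0, a, c, s, source,
#' background covariates and their mask); `visits.tsv` holds one row per
#' visit with one column per health variable, missing entries written as
#' empty fields.
#'
#' @param ch a `cohort`.
#' @param dir directory to write into (created if needed).
#' @param var_names optional health-variable names (default `v1..vN`).
#' @return `read_cohort` returns the `cohort`.
#' @export
write_cohort <- function(ch, dir, var_names = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- n_vars(ch)
  vn <- var_names %||% paste0("v", seq_len(N))
  B <- ncol(ch$u)
  ind <- data.frame(id = ch$id, t0 = ch$t0, a = ch$a, c = ch$c, s = ch$s,
                    source = ch$source)
  U <- ch$u
  U[ch$umask == 0] <- NA
  colnames(U) <- paste0("u_", seq_len(B))
  ind <- cbind(ind, U)
  utils::write.table(ind, file.path(dir, "individuals.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  vis <- do.call(rbind, lapply(seq_along(ch$id), function(m) {
    Y <- ch$y[[m]]
    Y[ch$o[[m]] == 0] <- NA
    data.frame(id = ch$id[m], age = ch$times[[m]], Y)
  }))
  names(vis) <- c("id", "age", vn)
  utils::write.table(vis, file.path(dir, "visits.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ind <- utils::read.table(file.path(dir, "individuals.tsv"), sep = "\t",
                           header = TRUE, colClasses = NA, na.strings = "")
  vis <- utils::read.table(file.path(dir, "visits.tsv"), sep = "\t",
                           header = TRUE, na.strings = "")
  ucols <- grep("^u_", names(ind))
  U <- as.matrix(ind[, ucols, drop = FALSE])
  dimnames(U) <- NULL
  umask <- 1 * !is.na(U)
  U[is.na(U)] <- 0
  ids <- as.character(ind$id)
  vids <- as.character(vis$id)
  vcols <- setdiff(names(vis), c("id", "age"))
  times <- y <- o <- vector("list", length(ids))
  for (m in seq_along(ids)) {
    rows <- which(vids == ids[m])
    rows <- rows[order(vis$age[rows])]
    times[[m]] <- vis$age[rows]
    Y <- as.matrix(vis[rows, vcols, drop = FALSE])
    O <- 1 * !is.na(Y)
    Y[is.na(Y)] <- 0
    dimnames(Y) <- NULL; dimnames(O) <- NULL
    y[[m]] <- Y; o[[m]] <- O
  }
  new_cohort(id = ids, t0 = ind$t0, times = times, y = y, o = o, u = U,
             umask = umask, a = ind$a, c = ind$c, s = ind$s,
             source = as.character(ind$source))
}
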
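# Minimal reverse-mode automatic differentiation on matrices.
#
# All model values are plain numeric matrices. When a tape is active,
# operations that touch an `adnode` record themselves; `ad_backward()`
# replays the tape in reverse accumulating gradients into leaves.
# With no tape active (or on plain inputs) every op computes eagerly and
# returns a plain matrix, so the same forward code serves both training
# (gradients) and prediction (fast, allocation-light).

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_begin <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 4096L)
  tp$n <- 0L
  .ad$tape <- tp
  invisible(tp)
}

ad_tape_end <- function() {
  tp <- .ad$tape
  .ad$tape <- NULL
  invisible(tp)
}

ad_active <- function() !is.null(.ad$tape)

# nodes are the only environments that flow through the ops, so environment
# dispatch is a fast class test
is.ad <- function(x) is.environment(x)

# value of a node or plain object
advl <- function(x) if (is.ad(x)) x$v else x

ad_node <- function(v, back = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd$back <- back
  class(nd) <- "adnode"
  tp <- .ad$tape
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd
}

# leaf (parameter) node: gradient accumulates here
ad_leaf <- function(v) {
  stopifnot(ad_active())
  ad_node(v)
}

ad_acc <- function(nd, g) {
  if (is.environment(nd)) nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

# Run reverse pass from scalar root. Leaves keep $g afterwards.
ad_backward <- function(root) {
  stopifnot(is.ad(root), length(root$v) == 1L)
  tp <- .ad$tape
  root$g <- 1
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$back)) nd$back(nd$g)
  }
  invisible(NULL)
}

# helper: reduce a broadcast gradient back to the shape of x
.ad_unbroadcast <- function(g, x) {
  if (length(x) == 1L) sum(g) else g
}

.rec <- function(...) {
  # should this call record? any ad arg while tape active
  if (is.null(.ad$tape)) return(FALSE)
  for (a in list(...)) if (is.environment(a)) return(TRUE)
  FALSE
}

## ---- arithmetic ----

ad_add <- function(a, b) {
  v <- advl(a) + advl(b)
  if (!.rec(a, b)) return(v)
  ad_node(v, function(G) {
    ad_acc(a, .ad_unbroadcast(G, advl(a)))
    ad_acc(b, .ad_unbroadcast(G, advl(b)))
  })
}

ad_sub <- function(a, b) {
  v <- advl(a) - advl(b)
  if (!.rec(a, b)) return(v)
  ad_node(v, function(G) {
    ad_acc(a, .ad_unbroadcast(G, advl(a)))
    ad_acc(b, .ad_unbroadcast(-G, advl(b)))
  })
}

ad_neg <- function(a) {
  v <- -advl(a)
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, -G))
}

ad_mul <- function(a, b) {
  av <- advl(a); bv <- advl(b)
  v <- av * bv
  if (!.rec(a, b)) return(v)
  ad_node(v, function(G) {
    ad_acc(a, .ad_unbroadcast(G * bv, av))
    ad_acc(b, .ad_unbroadcast(G * av, bv))
  })
}

ad_div <- function(a, b) {
  av <- advl(a); bv <- advl(b)
  v <- av / bv
  if (!.rec(a, b)) return(v)
  ad_node(v, function(G) {
    ad_acc(a, .ad_unbroadcast(G / bv, av))
    ad_acc(b, .ad_unbroadcast(-G * av / (bv * bv), bv))
  })
}

ad_matmul <- function(a, b) {
  av <- advl(a); bv <- advl(b)
  v <- av %*% bv
  if (!.rec(a, b)) return(v)
  ad_node(v, function(G) {
    ad_acc(a, G %*% t(bv))
    ad_acc(b, crossprod(av, G))
  })
}

# add row vector r (length ncol(X)) to every row of X
ad_addrow <- function(X, r) {
  Xv <- advl(X); rv <- advl(r)
  v <- Xv + rep(rv, each = nrow(Xv))
  if (!.rec(X, r)) return(v)
  ad_node(v, function(G) {
    ad_acc(X, G)
    ad_acc(r, colSums(G))
  })
}

# multiply each row of X elementwise by row vector r (length ncol(X))
ad_scalerow <- function(X, r) {
  Xv <- advl(X); rv <- advl(r)
  rb <- rep(as.vector(rv), each = nrow(Xv))
  v <- Xv * rb
  if (!.rec(X, r)) return(v)
  ad_node(v, function(G) {
    ad_acc(X, G * rb)
    g_r <- colSums(G * Xv)
    ad_acc(r, if (is.matrix(rv)) matrix(g_r, nrow = 1L) else g_r)
  })
}

# multiply each column of X elementwise by column vector s (length nrow(X))
ad_scalecol <- function(X, s) {
  Xv <- advl(X); sv <- advl(s)
  v <- Xv * as.vector(sv)
  if (!.rec(X, s)) return(v)
  ad_node(v, function(G) {
    ad_acc(X, G * as.vector(sv))
    ad_acc(s, matrix(rowSums(G * Xv), ncol = 1L))
  })
}

## ---- nonlinearities ----

ad_elu <- function(a) {
  av <- advl(a)
  neg <- av <= 0
  ex <- exp(av * neg)
  v <- av * !neg + (ex - 1) * neg
  if (!.rec(a)) return(v)
  d <- !neg + ex * neg
  ad_node(v, function(G) ad_acc(a, G * d))
}

ad_tanh <- function(a) {
  v <- tanh(advl(a))
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, G * (1 - v * v)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-advl(a)))
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, G * v * (1 - v)))
}

ad_exp <- function(a) {
  v <- exp(advl(a))
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, G * v))
}

ad_log <- function(a) {
  av <- advl(a)
  v <- log(av)
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, G / av))
}

ad_softplus <- function(a) {
  av <- advl(a)
  v <- ifelse(av > 30, av, log1p(exp(pmin(av, 30))))
  if (!.rec(a)) return(v)
  d <- 1 / (1 + exp(-av))
  ad_node(v, function(G) ad_acc(a, G * d))
}

ad_sq <- function(a) {
  av <- advl(a)
  v <- av * av
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, 2 * G * av))
}

ad_abs <- function(a) {
  av <- advl(a)
  v <- abs(av)
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, G * sign(av)))
}

ad_sqrt <- function(a) {
  v <- sqrt(advl(a))
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, G / (2 * v)))
}

# clamp with zero gradient outside [lo, hi]
ad_clamp <- function(a, lo, hi) {
  av <- advl(a)
  v <- pmin(pmax(av, lo), hi)
  if (!.rec(a)) return(v)
  d <- (av >= lo) & (av <= hi)
  ad_node(v, function(G) ad_acc(a, G * d))
}

ad_lgamma <- function(a) {
  av <- advl(a)
  v <- lgamma(av)
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, G * digamma(av)))
}

ad_digamma <- function(a) {
  av <- advl(a)
  v <- digamma(av)
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, G * trigamma(av)))
}

## ---- reductions and shaping ----

ad_sum <- function(a) {
  av <- advl(a)
  v <- sum(av)
  if (!.rec(a)) return(v)
  ad_node(v, function(G) {
    g <- if (is.matrix(av)) matrix(as.numeric(G), nrow(av), ncol(av))
         else rep(as.numeric(G), length(av))
    ad_acc(a, g)
  })
}

ad_rowSums <- function(a) {
  av <- advl(a)
  v <- matrix(rowSums(av), ncol = 1L)
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, matrix(as.vector(G), nrow(av), ncol(av))))
}

ad_colSums <- function(a) {
  av <- advl(a)
  v <- matrix(colSums(av), nrow = 1L)
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, matrix(as.vector(G), nrow(av), ncol(av), byrow = TRUE)))
}

# column-bind nodes/matrices (all same nrow)
ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, advl)
  v <- do.call(cbind, vals)
  if (!.rec(...)) return(v)
  ncols <- vapply(vals, function(m) ncol(m) %||% 1L, integer(1))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ad_node(v, function(G) {
    for (i in seq_along(args)) {
      ad_acc(args[[i]], G[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_t <- function(a) {
  v <- t(advl(a))
  if (!.rec(a)) return(v)
  ad_node(v, function(G) ad_acc(a, t(G)))
}

# select columns of a node/matrix
ad_cols <- function(a, idx) {
  av <- advl(a)
  v <- av[, idx, drop = FALSE]
  if (!.rec(a)) return(v)
  ad_node(v, function(G) {
    Z <- matrix(0, nrow(av), ncol(av))
    Z[, idx] <- Z[, idx] + G
    ad_acc(a, Z)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
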
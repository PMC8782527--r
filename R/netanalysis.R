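# Posterior network extraction: Laplace credible intervals, pruning of
# non-robust edges, hierarchical clustering of the robust weights, and
# plain-text exports.

#' Central Laplace credible interval
#'
#' For a Laplace(m, b) posterior the central interval at `level` is
#' `[m + b log(2q), m - b log(2q)]` with `q = (1 - level)/2`.
#'
#' @param m posterior location(s).
#' @param b posterior scale(s), > 0.
#' @param level credible level in (0, 1).
#' @return list with vectors/matrices `lo`, `hi`.
#' @export
credible_interval <- function(m, b, level = 0.99) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  q <- (1 - level) / 2
  list(lo = m + b * log(2 * q), hi = m - b * log(2 * q))
}

as_posterior <- function(x) {
  if (inherits(x, "trajnet")) {
    list(W_bar = x$posterior$W_bar, b = x$posterior$b)
  } else {
    stopifnot(is.list(x), !is.null(x$W_bar), !is.null(x$b))
    x
  }
}

#' Prune non-robust interaction weights
#'
#' An edge is retained only when its central credible interval excludes zero;
#' retained-edge signs are the signs of the posterior means. The diagonal is
#' excluded from the edge set.
#'
#' @param x a fitted `trajnet` or a list with `W_bar` and `b` matrices.
#' @param level credible level (default 0.99).
#' @return list of class `interaction_posterior`: `W_bar`, `b`,
#'   `pruned_mask` (binary, 1 = robust), `W_robust` (means with pruned
#'   entries zeroed), `level`.
#' @export
prune_network <- function(x, level = 0.99) {
  ps <- as_posterior(x)
  W <- ps$W_bar; b <- ps$b
  N <- nrow(W)
  ci <- credible_interval(W, ifelse(is.na(b), 1, b), level)
  keep <- (ci$lo > 0 | ci$hi < 0) & row(W) != col(W) & !is.na(b)
  Wr <- ifelse(keep, W, 0)
  structure(list(W_bar = W, b = b, pruned_mask = 1 * keep, W_robust = Wr,
                 level = level),
            class = "interaction_posterior")
}

#' Hierarchically cluster the robust interaction network
#'
#' Symmetrizes `omega = (W^T + W)/2` on the absolute robust posterior means,
#' converts to the dissimilarity `D = max(omega) - omega`, and applies
#' average-linkage agglomerative clustering. Merge ties resolve to the
#' lowest-index pair (the default deterministic behaviour of [stats::hclust]).
#'
#' @param W an N x N weight matrix (absolute robust means), a fitted
#'   `trajnet`, or an `interaction_posterior`.
#' @return list: `hclust` (the merge tree), `order` (leaf order for heatmap
#'   display), `omega`, `D`.
#' @export
cluster_network <- function(W) {
  if (inherits(W, "trajnet")) W <- abs(prune_network(W)$W_robust)
  if (inherits(W, "interaction_posterior")) W <- abs(W$W_robust)
  if (nrow(W) < 2) stop("need at least two variables to cluster")
  omega <- (t(W) + W) / 2
  D <- max(omega) - omega
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  list(hclust = hc, order = hc$order, omega = omega, D = D)
}

#' Export the posterior network as an edge list
#'
#' @param x a fitted `trajnet` or posterior list.
#' @param level credible level for the robustness flag.
#' @param names optional variable names.
#' @param path optional file; if given, the edge list is written as
#'   tab-separated text.
#' @return data frame: source, target, mean, scale, lo, hi, sign, robust.
#' @export
export_edges <- function(x, level = 0.99, names = NULL, path = NULL) {
  ps <- as_posterior(x)
  N <- nrow(ps$W_bar)
  nms <- names %||% paste0("v", seq_len(N))
  pr <- prune_network(ps, level)
  ci <- credible_interval(ps$W_bar, ifelse(is.na(ps$b), 1, ps$b), level)
  off <- which(row(ps$W_bar) != col(ps$W_bar))
  df <- data.frame(
    source = nms[col(ps$W_bar)[off]], target = nms[row(ps$W_bar)[off]],
    mean = ps$W_bar[off], scale = ps$b[off], lo = ci$lo[off], hi = ci$hi[off],
    sign = sign(ps$W_bar[off]), robust = pr$pruned_mask[off] == 1
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  df
}

#' Export the clustering merge tree as a newick string
#'
#' @param cl a [cluster_network()] result.
#' @param names optional leaf names.
#' @return newick tree string.
#' @export
export_tree <- function(cl, names = NULL) {
  hc <- cl$hclust
  n <- length(hc$order)
  lab <- names %||% paste0("v", seq_len(n))
  node_str <- character(nrow(hc$merge))
  leaf <- function(i) lab[-i]
  for (k in seq_len(nrow(hc$merge))) {
    ch <- hc$merge[k, ]
    str <- vapply(ch, function(ci) if (ci < 0) leaf(ci) else node_str[ci],
                  character(1))
    node_str[k] <- paste0("(", str[1], ",", str[2], "):", round(hc$height[k], 6))
  }
  paste0(sub(":[^:]*$", "", node_str[nrow(hc$merge)]), ";")
}
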
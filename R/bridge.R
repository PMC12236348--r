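# Bridge centralities: expected influence, closeness, betweenness, and the
# bootstrapped pairwise difference test.

# Path-length convention: included edges have length 1/|weight|; absent
# edges are infinite. Returns all-pairs shortest-path distances and
# geodesic counts (fractional-tie machinery for betweenness).
shortest_path_data <- function(w_signed, tol = 1e-10) {
  w <- abs(w_signed)
  p <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0

  # Floyd-Warshall distances.
  d <- len
  for (k in seq_len(p)) {
    for (i in seq_len(p)) {
      dk <- d[i, k]
      if (is.finite(dk)) {
        nd <- dk + d[k, ]
        upd <- nd < d[i, ]
        d[i, upd] <- nd[upd]
      }
    }
  }

  # Geodesic counts sigma[s, v] by dynamic programming in distance order.
  sigma <- matrix(0, p, p)
  for (s in seq_len(p)) {
    ord <- order(d[s, ])
    sigma[s, s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      preds <- which(is.finite(len[, v]) & len[, v] > 0)
      for (u in preds) {
        if (abs(d[s, u] + len[u, v] - d[s, v]) <= tol * (1 + d[s, v])) {
          sigma[s, v] <- sigma[s, v] + sigma[s, u]
        }
      }
    }
  }
  list(d = d, sigma = sigma, len = len, tol = tol)
}

# Resolve the (signed) selected weight matrix and a membership vector.
bridge_inputs <- function(network, partition) {
  w <- if (inherits(network, "estimated_network")) {
    selected_weights(network)
  } else {
    as.matrix(network)
  }
  diag(w) <- 0
  check_symmetric(w, "weight matrix")
  membership <- if (inherits(partition, "community_partition")) {
    partition$membership
  } else {
    partition
  }
  if (length(membership) != nrow(w)) {
    stop("partition length must match the node count", call. = FALSE)
  }
  list(w = w, membership = as.integer(membership))
}

#' Bridge expected influence
#'
#' Signed sum of a node's selected edge weights to nodes outside its own
#' community — the direct cross-community influence of the node.
#'
#' @param network An `estimated_network` or signed symmetric weight matrix.
#' @param partition A `community_partition` or integer membership vector.
#' @return Named numeric vector, one value per node.
#' @export
bridge_expected_influence <- function(network, partition) {
  bi <- bridge_inputs(network, partition)
  p <- nrow(bi$w)
  out <- vapply(seq_len(p), function(i) {
    sum(bi$w[i, bi$membership != bi$membership[i]])
  }, numeric(1))
  stats::setNames(out, colnames(bi$w))
}

#' Bridge closeness
#'
#' Inverse of the mean shortest-path distance (edge length 1/|weight|) from
#' a node to every node outside its community. If any out-community node is
#' unreachable the mean distance is infinite and the value is 0 by
#' convention.
#'
#' @inheritParams bridge_expected_influence
#' @return Named numeric vector.
#' @export
bridge_closeness <- function(network, partition) {
  bi <- bridge_inputs(network, partition)
  sp <- shortest_path_data(bi$w)
  p <- nrow(bi$w)
  out <- vapply(seq_len(p), function(i) {
    others <- which(bi$membership != bi$membership[i])
    if (!length(others)) return(0)
    md <- mean(sp$d[i, others])
    if (is.finite(md) && md > 0) 1 / md else 0
  }, numeric(1))
  stats::setNames(out, colnames(bi$w))
}

#' Bridge betweenness
#'
#' Number of shortest paths between node pairs lying in different
#' communities that pass through the node (endpoints excluded). Tied
#' geodesics are counted fractionally, so values need not be integers.
#'
#' @inheritParams bridge_expected_influence
#' @return Named numeric vector.
#' @export
bridge_betweenness <- function(network, partition) {
  bi <- bridge_inputs(network, partition)
  sp <- shortest_path_data(bi$w)
  p <- nrow(bi$w)
  out <- numeric(p)
  for (s in seq_len(p - 1L)) {
    for (t in seq.int(s + 1L, p)) {
      if (bi$membership[s] == bi$membership[t]) next
      if (!is.finite(sp$d[s, t]) || sp$sigma[s, t] == 0) next
      for (v in seq_len(p)) {
        if (v == s || v == t) next
        on_path <- abs(sp$d[s, v] + sp$d[v, t] - sp$d[s, t]) <=
          sp$tol * (1 + sp$d[s, t])
        if (on_path && is.finite(sp$d[s, v]) && is.finite(sp$d[v, t])) {
          out[v] <- out[v] + sp$sigma[s, v] * sp$sigma[v, t] / sp$sigma[s, t]
        }
      }
    }
  }
  stats::setNames(out, colnames(bi$w))
}

#' All three bridge centralities of a network
#'
#' @inheritParams bridge_expected_influence
#' @return Data frame with `node`, `bei` (bridge expected influence),
#'   `bcl` (bridge closeness) and `bbw` (bridge betweenness); attribute
#'   `"distance"` records the 1/|weight| path-length convention.
#' @export
bridge_scores <- function(network, partition) {
  out <- data.frame(
    node = names(bridge_expected_influence(network, partition)),
    bei = unname(bridge_expected_influence(network, partition)),
    bcl = unname(bridge_closeness(network, partition)),
    bbw = unname(bridge_betweenness(network, partition)),
    stringsAsFactors = FALSE
  )
  attr(out, "distance") <- "1/|weight| on included edges"
  out
}

#' Bootstrapped pairwise difference test for a bridge metric
#'
#' Tests, for every pair of nodes, whether their bridge-centrality values
#' differ: participants are resampled with replacement, the partial
#' Spearman correlations are re-estimated with the full-sample edge
#' inclusion mask applied (no re-selection, so model-selection variability
#' is not mixed into the difference test), the community partition is held
#' fixed, and the metric is recomputed. A pair differs significantly when
#' the central percentile interval of the bootstrap difference excludes 0.
#'
#' @param table Subscale data the network was estimated from.
#' @param network The full-sample `estimated_network` (supplies the
#'   inclusion mask).
#' @param partition The full-sample `community_partition` (held fixed).
#' @param metric One of `"bei"`, `"bcl"`, `"bbw"`.
#' @param n_boot Bootstrap replicates; default 5000.
#' @param ci Central coverage of the percentile interval; default 0.95.
#' @param seed Integer seed.
#' @return A `bridge_diff_result`: `metric`, `estimate` (full-sample
#'   per-node values), `diff` (matrix of row minus column differences),
#'   `ci_lower`/`ci_upper`, `significant` (logical matrix), `n_boot`,
#'   `seed`.
#' @export
bridge_difference_test <- function(table, network, partition,
                                   metric = c("bei", "bcl", "bbw"),
                                   n_boot = 5000, ci = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(inherits(network, "estimated_network"))
  x <- subscale_matrix(table, network$node_labels)
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  membership <- if (inherits(partition, "community_partition")) {
    partition$membership
  } else partition

  metric_fun <- switch(metric,
    bei = bridge_expected_influence,
    bcl = bridge_closeness,
    bbw = bridge_betweenness
  )
  mask <- network$included

  est <- metric_fun(network, membership)
  boot <- matrix(NA_real_, as.integer(n_boot), p)
  set.seed(as.integer(seed))
  for (b in seq_len(as.integer(n_boot))) {
    rows <- sample.int(n, n, replace = TRUE)
    pc <- partial_correlations(spearman_correlations(x[rows, , drop = FALSE]))
    diag(pc) <- 0
    boot[b, ] <- metric_fun(pc * mask, membership)
  }

  probs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  lower <- upper <- diffm <- matrix(
    0, p, p, dimnames = list(network$node_labels, network$node_labels))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      dd <- boot[, i] - boot[, j]
      qs <- quantile(dd, probs = probs, names = FALSE)
      lower[i, j] <- qs[1]; upper[i, j] <- qs[2]
      diffm[i, j] <- est[i] - est[j]
    }
  }
  significant <- lower > 0 | upper < 0
  diag(significant) <- FALSE

  structure(
    list(metric = metric, estimate = est, diff = diffm,
         ci_lower = lower, ci_upper = upper, significant = significant,
         n_boot = as.integer(n_boot), ci = ci, seed = as.integer(seed)),
    class = "bridge_diff_result"
  )
}

#' @export
print.bridge_diff_result <- function(x, ...) {
  n_sig <- sum(x$significant[upper.tri(x$significant)])
  cat(sprintf(
    "Bootstrapped %s differences: %d/%d node pairs significant (%d replicates)\n",
    toupper(x$metric), n_sig,
    sum(upper.tri(x$significant)), x$n_boot))
  invisible(x)
}
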
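# Independent oracles used by the unit and acceptance tests. These are
# deliberately written via different routes than the implementation
# (Schur complements, exhaustive enumeration, truncated series).

# Partial correlation of variables i and j given the rest, via the Schur
# complement of the covariance (the "residual correlation" route).
oracle_partial <- function(sigma, i, j) {
  rest <- setdiff(seq_len(ncol(sigma)), c(i, j))
  s <- sigma[c(i, j), c(i, j)]
  if (length(rest)) {
    s <- s - sigma[c(i, j), rest, drop = FALSE] %*%
      solve(sigma[rest, rest]) %*% sigma[rest, c(i, j), drop = FALSE]
  }
  s[1, 2] / sqrt(s[1, 1] * s[2, 2])
}

# Random positive-definite correlation matrix.
random_pd_corr <- function(p, jitter = 1) {
  a <- matrix(rnorm(p * p), p)
  stats::cov2cor(crossprod(a) + jitter * p * diag(p))
}

# All set partitions of n elements as membership vectors (restricted
# growth strings). Bell(8) = 4140, fine for exhaustive modularity search.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (c in seq_len(maxc + 1L)) {
      rec(c(prefix, c), max(maxc, c))
    }
  }
  rec(integer(), 0L)
  out
}

# Canonical form of a membership vector (community ids in order of first
# appearance) so partitions can be compared up to relabeling.
canonical_partition <- function(membership) {
  match(membership, unique(membership))
}

# Exhaustive bridge betweenness by enumerating every simple path between
# all cross-community node pairs (edge length 1/|weight|).
oracle_bridge_betweenness <- function(w, membership, tol = 1e-10) {
  w <- abs(w)
  p <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  paths_between <- function(s, t) {
    res <- list()
    walk <- function(path, dist) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1L]] <<- list(path = path, dist = dist)
        return(invisible())
      }
      for (u in seq_len(p)) {
        if (is.finite(len[v, u]) && len[v, u] > 0 && !(u %in% path)) {
          walk(c(path, u), dist + len[v, u])
        }
      }
    }
    walk(s, 0)
    res
  }
  bbw <- numeric(p)
  for (s in seq_len(p - 1L)) {
    for (t in seq.int(s + 1L, p)) {
      if (membership[s] == membership[t]) next
      ps <- paths_between(s, t)
      if (!length(ps)) next
      dmin <- min(vapply(ps, `[[`, numeric(1), "dist"))
      geo <- Filter(function(x) x$dist <= dmin * (1 + tol) + tol, ps)
      for (g in geo) {
        inner <- setdiff(g$path, c(s, t))
        bbw[inner] <- bbw[inner] + 1 / length(geo)
      }
    }
  }
  bbw
}

# Truncated power-series average controllability: sum_tau ||A^tau e_i||^2.
oracle_avg_ctrl_series <- function(a, t_max = 200) {
  p <- nrow(a)
  pw <- diag(p)
  acc <- numeric(p)
  for (tau in 0:t_max) {
    acc <- acc + colSums(pw^2)
    pw <- a %*% pw
  }
  acc
}

# Small labelled symmetric weight matrix builder for graph tests.
edge_matrix <- function(labels, edges) {
  p <- length(labels)
  w <- matrix(0, p, p, dimnames = list(labels, labels))
  for (e in edges) {
    w[e[[1]], e[[2]]] <- w[e[[2]], e[[1]]] <- e[[3]]
  }
  w
}
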
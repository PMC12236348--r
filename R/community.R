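# Fast greedy (Clauset-Newman-Moore) modularity community detection with a
# pinned deterministic tie-break.

#' Newman-Girvan modularity of a partition
#'
#' Q = (1/2m) sum_ij (w_ij - k_i k_j / 2m) delta(c_i, c_j), with m the total
#' edge weight and k the weighted degrees. Weights must be nonnegative;
#' signed networks are handled upstream by taking absolute values.
#'
#' @param weights Symmetric nonnegative weight matrix with zero diagonal,
#'   or an `estimated_network` (absolute selected weights are used).
#' @param membership Integer community assignment, one entry per node.
#' @return Modularity Q.
#' @export
modularity_q <- function(weights, membership) {
  w <- community_weights(weights)
  if (length(membership) != nrow(w)) {
    stop("membership length must match the node count", call. = FALSE)
  }
  m2 <- sum(w)
  if (m2 <= 0) stop("modularity undefined for an empty network", call. = FALSE)
  k <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - outer(k, k) / m2) * same) / m2
}

# Nonnegative weight matrix used for community detection.
community_weights <- function(network) {
  w <- if (inherits(network, "estimated_network")) {
    abs(selected_weights(network))
  } else {
    abs(as.matrix(network))
  }
  check_symmetric(w, "weight matrix")
  diag(w) <- 0
  w
}

#' Fast greedy community detection
#'
#' Agglomerative Clauset-Newman-Moore modularity maximization on the
#' absolute selected edge weights: starting from singletons, repeatedly
#' merge the pair of communities with the largest modularity gain and cut
#' the merge dendrogram at the maximum-Q level (the earliest such level, so
#' zero-gain merges of isolated nodes are not applied). Ties in the gain
#' are broken deterministically: the merge whose pair of community labels
#' (each community labelled by its lexicographically smallest node) sorts
#' first wins.
#'
#' @param network An `estimated_network` or a symmetric weight matrix;
#'   absolute values are used. Must contain at least one nonzero edge.
#' @return A `community_partition`: `membership` (named integer vector with
#'   consecutive community ids in order of first appearance), `Q`,
#'   `n_communities` and `merge_history` (data frame: step, the two merged
#'   community labels, Q after the merge).
#' @examples
#' w <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
#' w["a", "b"] <- w["b", "a"] <- 1
#' w["c", "d"] <- w["d", "c"] <- 1
#' fast_greedy(w)$n_communities
#' @export
fast_greedy <- function(network) {
  w <- community_weights(network)
  p <- nrow(w)
  labs <- colnames(w)
  if (is.null(labs)) labs <- paste0("V", seq_len(p))
  if (sum(w) <= 0) stop("cannot detect communities in an empty network",
                        call. = FALSE)

  cur <- seq_len(p)
  levels_membership <- list(cur)
  q_levels <- modularity_q(w, cur)
  merge_history <- data.frame(step = integer(), from = character(),
                              into = character(), Q = numeric(),
                              stringsAsFactors = FALSE)

  comm_label <- function(membership, id) {
    min(labs[membership == id])
  }

  for (step in seq_len(p - 1L)) {
    ids <- sort(unique(cur))
    best <- NULL
    for (ai in seq_len(length(ids) - 1L)) {
      for (bi in seq.int(ai + 1L, length(ids))) {
        a <- ids[ai]; b <- ids[bi]
        cand <- cur
        cand[cand == b] <- a
        q <- modularity_q(w, cand)
        la <- comm_label(cur, a); lb <- comm_label(cur, b)
        key <- sort(c(la, lb))
        if (is.null(best) || q > best$q + 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(q = q, a = a, b = b, key = key, cand = cand)
        }
      }
    }
    cur <- best$cand
    q_levels <- c(q_levels, best$q)
    levels_membership[[step + 1L]] <- cur
    merge_history <- rbind(merge_history, data.frame(
      step = step, from = best$key[2], into = best$key[1], Q = best$q,
      stringsAsFactors = FALSE))
  }

  best_level <- which.max(q_levels)  # first maximum: earliest level
  membership <- levels_membership[[best_level]]
  membership <- match(membership, unique(membership))
  names(membership) <- labs

  structure(
    list(membership = membership,
         Q = q_levels[best_level],
         n_communities = length(unique(membership)),
         merge_history = merge_history,
         q_levels = q_levels),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d communities, Q = %.4f\n",
              x$n_communities, x$Q))
  for (cid in sort(unique(x$membership))) {
    cat(sprintf("  [%d] %s\n", cid,
                paste(names(x$membership)[x$membership == cid],
                      collapse = ", ")))
  }
  invisible(x)
}
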
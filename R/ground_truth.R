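# Ground-truth network construction for the synthetic-data generator.

#' Default cross-instrument bridge edges of the generating network
#'
#' The generating topology places all cross-instrument dependence on a small
#' set of bridge edges, with the social-production subscale (SocProd)
#' carrying the strongest links between self-reported gestures, task
#' performance and schizotypal traits.
#'
#' @return Data frame with columns `from`, `to`, `weight` (partial
#'   correlations).
#' @export
default_bridge_edges <- function() {
  data.frame(
    from   = c("SocProd", "SocProd", "SocProd", "Disorg", "Interp",
               "Prod", "Prod", "Prod"),
    to     = c("Icon", "Metaph", "CogPerc", "Metaph", "Perc",
               "Icon", "Disorg", "Interp"),
    weight = c(0.15, 0.12, 0.12, -0.10, -0.10, -0.10, 0.10, -0.10),
    stringsAsFactors = FALSE
  )
}

#' Construct a ground-truth partial-correlation network
#'
#' Builds a known 9-node partial-correlation matrix with three instrument
#' blocks (SPQ-B, BAG, task). Within-block partial correlations are drawn
#' uniformly from `within_strength`; cross-block entries are zero except for
#' the listed bridge edges. The implied precision matrix (unit diagonal,
#' off-diagonal minus the partial correlations) must be positive definite;
#' a request that is not is rejected, never silently repaired.
#'
#' @param within_strength Length-2 numeric interval (or a single value) of
#'   within-block partial correlations; default `c(0.2, 0.4)`.
#' @param bridge_edges Data frame with columns `from`, `to`, `weight`, as
#'   returned by [default_bridge_edges()]. May have zero rows.
#' @param seed Integer seed controlling the within-block draws.
#' @return An object of class `ground_truth_network` with elements
#'   `node_labels`, `pcor` (symmetric, unit diagonal), `communities`
#'   (instrument blocks) and `zero_mask` (TRUE where the partial
#'   correlation is structurally zero).
#' @examples
#' gt <- make_ground_truth()
#' gt$pcor["SocProd", "Icon"]
#' @export
make_ground_truth <- function(within_strength = c(0.2, 0.4),
                              bridge_edges = default_bridge_edges(),
                              seed = 42L) {
  labels <- node_labels()
  blocks <- instrument_blocks()
  p <- length(labels)
  if (length(within_strength) == 1L) {
    within_strength <- rep(within_strength, 2L)
  }
  if (length(within_strength) != 2L || within_strength[1] > within_strength[2]) {
    stop("within_strength must be a value or an increasing length-2 interval",
         call. = FALSE)
  }

  pcor <- diag(p)
  dimnames(pcor) <- list(labels, labels)

  set.seed(as.integer(seed))
  for (b in sort(unique(blocks))) {
    members <- labels[blocks == b]
    if (length(members) < 2L) next
    for (i in seq_len(length(members) - 1L)) {
      for (j in seq.int(i + 1L, length(members))) {
        w <- runif(1L, within_strength[1], within_strength[2])
        pcor[members[i], members[j]] <- w
        pcor[members[j], members[i]] <- w
      }
    }
  }

  if (nrow(bridge_edges)) {
    bad <- setdiff(unique(c(bridge_edges$from, bridge_edges$to)), labels)
    if (length(bad)) {
      stop("unknown bridge-edge nodes: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (k in seq_len(nrow(bridge_edges))) {
      i <- bridge_edges$from[k]
      j <- bridge_edges$to[k]
      pcor[i, j] <- bridge_edges$weight[k]
      pcor[j, i] <- bridge_edges$weight[k]
    }
  }

  if (any(abs(pcor[upper.tri(pcor)]) >= 1)) {
    stop("partial correlations must lie in (-1, 1)", call. = FALSE)
  }

  # Precision matrix implied by the requested partial correlations.
  prec <- -pcor
  diag(prec) <- 1
  ev <- eigen(prec, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(
      "requested partial correlations do not define a positive-definite precision matrix (minimum eigenvalue %.3e)",
      min(ev)), call. = FALSE)
  }

  zero_mask <- pcor == 0
  diag(zero_mask) <- FALSE

  structure(
    list(node_labels = labels, pcor = pcor, communities = blocks,
         zero_mask = zero_mask, seed = as.integer(seed)),
    class = "ground_truth_network"
  )
}

#' @export
print.ground_truth_network <- function(x, ...) {
  n_edges <- sum(x$pcor[upper.tri(x$pcor)] != 0)
  cat("Ground-truth partial-correlation network\n")
  cat(sprintf("  %d nodes, %d nonzero edges, %d instrument blocks\n",
              length(x$node_labels), n_edges, length(unique(x$communities))))
  invisible(x)
}

#' Serialize a ground-truth network to disk
#'
#' Writes `<prefix>.json` (labels, partial-correlation matrix, block
#' assignment, zero mask) and `<prefix>_edges.tsv` (weighted edge list of
#' the nonzero partial correlations).
#'
#' @param gt A `ground_truth_network`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_ground_truth <- function(gt, prefix) {
  stopifnot(inherits(gt, "ground_truth_network"))
  json_path <- paste0(prefix, ".json")
  tsv_path <- paste0(prefix, "_edges.tsv")
  jsonlite::write_json(
    list(node_labels = gt$node_labels,
         pcor = gt$pcor,
         communities = as.list(gt$communities),
         zero_mask = gt$zero_mask,
         seed = gt$seed),
    json_path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  idx <- which(upper.tri(gt$pcor) & gt$pcor != 0, arr.ind = TRUE)
  edges <- data.frame(node1 = gt$node_labels[idx[, 1]],
                      node2 = gt$node_labels[idx[, 2]],
                      weight = gt$pcor[idx])
  utils::write.table(edges, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(json_path, tsv_path))
}

#' Covariance matrix implied by a ground-truth network
#'
#' Inverts the partial-correlation parameterization: the precision matrix
#' with unit diagonal and off-diagonal entries minus the partial
#' correlations is inverted and rescaled to unit variances, so that
#' standardizing the negated inverse of the result recovers the generating
#' partial correlations.
#'
#' @param gt A `ground_truth_network`.
#' @return Symmetric positive-definite covariance (= correlation) matrix.
#' @export
pcor_to_covariance <- function(gt) {
  stopifnot(inherits(gt, "ground_truth_network"))
  prec <- -gt$pcor
  diag(prec) <- 1
  sigma <- tryCatch(solve(prec), error = function(e) {
    stop("precision matrix is singular; cannot form a covariance",
         call. = FALSE)
  })
  sigma <- stats::cov2cor(sigma)
  dimnames(sigma) <- dimnames(gt$pcor)
  (sigma + t(sigma)) / 2
}
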
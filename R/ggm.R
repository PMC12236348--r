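# Non-regularized partial Spearman correlation network with bootstrap
# percentile-interval edge selection.

#' Repair a symmetric matrix to positive definiteness
#'
#' Eigenvalues below `floor` are clipped to `floor`, the matrix is
#' reassembled and its diagonal renormalized to 1. A matrix that is already
#' positive definite is returned unchanged. Used to stabilize occasional
#' indefinite Spearman correlation matrices in bootstrap resamples.
#'
#' @param m Symmetric matrix.
#' @param floor Minimum eigenvalue after repair; default `1e-8`.
#' @return Symmetric positive-definite matrix with unit diagonal (when the
#'   input had one); attribute `"repaired"` is TRUE when clipping occurred.
#' @export
nearest_positive_definite <- function(m, floor = 1e-8) {
  check_symmetric(m, "correlation matrix")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) {
    attr(m, "repaired") <- FALSE
    return(m)
  }
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- stats::cov2cor(out)
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  attr(out, "repaired") <- TRUE
  out
}

#' Partial correlations from a correlation matrix
#'
#' Inverts the correlation matrix and standardizes the negated inverse:
#' with P = corr^-1, partial(i, j) = -P(i, j) / sqrt(P(i, i) P(j, j)).
#' A non-positive-definite input is first routed through
#' [nearest_positive_definite()].
#'
#' @param corr Symmetric correlation matrix.
#' @param floor Eigenvalue floor for the repair step.
#' @return Symmetric partial-correlation matrix with unit diagonal;
#'   attribute `"repaired"` records whether the input needed repair.
#' @export
partial_correlations <- function(corr, floor = 1e-8) {
  check_symmetric(corr, "correlation matrix")
  corr <- nearest_positive_definite(corr, floor = floor)
  repaired <- isTRUE(attr(corr, "repaired"))
  prec <- tryCatch(solve(corr), error = function(e) {
    stop("correlation matrix is singular even after repair", call. = FALSE)
  })
  d <- 1 / sqrt(diag(prec))
  pc <- -prec * outer(d, d)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- dimnames(corr)
  attr(pc, "repaired") <- repaired
  pc
}

# Spearman correlation matrix of an observation matrix (midranks).
spearman_correlations <- function(x) {
  cor(rank_columns(x))
}

#' Estimate the network with bootstrap percentile edge selection
#'
#' Estimates the non-regularized partial Spearman correlation network over
#' the subscale variables and applies the percentile-interval decision rule
#' for edge inclusion: rows are resampled with replacement `n_boot` times,
#' the Spearman correlation matrix of each resample (repaired by eigenvalue
#' clipping if indefinite) is converted to partial correlations, and an edge
#' is retained iff the central `ci` percentile interval of its bootstrap
#' distribution excludes zero. Retained edges carry the full-sample partial
#' correlation (not the bootstrap mean); excluded edges are zero in the
#' selected graph view.
#'
#' @param table Subscale data frame (see [simulate_subscales()] /
#'   [score_responses()]) or numeric matrix with the node columns.
#' @param n_boot Number of bootstrap resamples; default 5000.
#' @param ci Central coverage of the percentile interval; default 0.95.
#' @param alpha Decision level; must equal `1 - ci` unless
#'   `allow_ci_alpha_mismatch = TRUE`.
#' @param seed Integer seed; the result is bit-reproducible given the seed.
#' @param labels Node columns to use; defaults to [node_labels()] when
#'   present, otherwise all numeric columns.
#' @param allow_ci_alpha_mismatch Permit `ci != 1 - alpha`.
#' @return An `estimated_network`: `node_labels`, `pcor` (full-sample
#'   partial correlations, unit diagonal), `weights` (zero-diagonal graph
#'   view of `pcor`), `included` (logical edge mask), `ci_lower`/`ci_upper`
#'   (percentile bounds), `n`, `n_boot`, `ci`, `alpha`, `seed`,
#'   `repair_count` (bootstrap resamples needing eigenvalue clipping) and
#'   `redraw_count` (resamples redrawn because a column was constant).
#' @examples
#' gt <- make_ground_truth()
#' tab <- simulate_subscales(gt, 300, seed = 7)
#' net <- bootstrap_edge_selection(tab, n_boot = 200, seed = 7)
#' sum(net$included[upper.tri(net$included)])
#' @export
bootstrap_edge_selection <- function(table, n_boot = 5000, ci = 0.95,
                                     alpha = 0.05, seed = 1L,
                                     labels = NULL,
                                     allow_ci_alpha_mismatch = FALSE) {
  if (is.null(labels)) {
    labels <- if (is.data.frame(table) && all(node_labels() %in% names(table))) {
      node_labels()
    } else if (is.matrix(table) && all(node_labels() %in% colnames(table))) {
      node_labels()
    } else {
      df <- as.data.frame(table)
      names(df)[vapply(df, is.numeric, logical(1))]
    }
  }
  x <- subscale_matrix(table, labels)
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (n < p) stop("fewer complete rows than nodes; network not estimable",
                  call. = FALSE)
  if (n < 10 * p) {
    warning(sprintf(
      "only %d complete rows for %d nodes; at least %d recommended", n, p,
      10 * p), call. = FALSE)
  }
  if (abs(ci - (1 - alpha)) > 1e-12 && !allow_ci_alpha_mismatch) {
    stop("ci must equal 1 - alpha (set allow_ci_alpha_mismatch = TRUE to override)",
         call. = FALSE)
  }
  n_boot <- as.integer(n_boot)

  full_corr <- spearman_correlations(x)
  full_pcor <- partial_correlations(full_corr)

  idx_ut <- which(upper.tri(full_pcor))
  boot <- matrix(NA_real_, n_boot, length(idx_ut))
  repair_count <- 0L
  redraw_count <- 0L

  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    for (try in seq_len(100L)) {
      rows <- sample.int(n, n, replace = TRUE)
      xb <- x[rows, , drop = FALSE]
      if (all(col_sds(xb) > 0)) break
      redraw_count <- redraw_count + 1L
      if (try == 100L) {
        stop("could not draw a bootstrap resample without a constant column",
             call. = FALSE)
      }
    }
    pc <- partial_correlations(spearman_correlations(xb))
    if (isTRUE(attr(pc, "repaired"))) repair_count <- repair_count + 1L
    boot[b, ] <- pc[idx_ut]
  }

  probs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  qs <- apply(boot, 2L, quantile, probs = probs, names = FALSE)

  ci_lower <- ci_upper <- matrix(0, p, p, dimnames = dimnames(full_pcor))
  ci_lower[idx_ut] <- qs[1, ]
  ci_upper[idx_ut] <- qs[2, ]
  ci_lower <- ci_lower + t(ci_lower)
  ci_upper <- ci_upper + t(ci_upper)

  included <- ci_lower > 0 | ci_upper < 0
  diag(included) <- FALSE

  weights <- full_pcor
  diag(weights) <- 0

  structure(
    list(node_labels = colnames(x), pcor = full_pcor, weights = weights,
         included = included, ci_lower = ci_lower, ci_upper = ci_upper,
         n = n, n_boot = n_boot, ci = ci, alpha = alpha,
         seed = as.integer(seed),
         repair_count = repair_count, redraw_count = redraw_count),
    class = "estimated_network"
  )
}

# Column standard deviations without extra dependencies.
col_sds <- function(x) {
  apply(x, 2L, sd)
}

#' Selected (sparsified) weight matrix of an estimated network
#'
#' @param network An `estimated_network` (returned unchanged if a plain
#'   symmetric matrix is supplied).
#' @return Symmetric matrix with the full-sample partial correlations on
#'   included edges and zero elsewhere (zero diagonal).
#' @export
selected_weights <- function(network) {
  if (is.matrix(network)) {
    w <- network
    diag(w) <- 0
    return(w)
  }
  stopifnot(inherits(network, "estimated_network"))
  network$weights * network$included
}

#' @export
print.estimated_network <- function(x, ...) {
  p <- length(x$node_labels)
  n_inc <- sum(x$included[upper.tri(x$included)])
  cat("Partial Spearman correlation network\n")
  cat(sprintf("  %d nodes, %d/%d edges included (n = %d, %d bootstraps, %.0f%% percentile CIs)\n",
              p, n_inc, p * (p - 1) / 2, x$n, x$n_boot, 100 * x$ci))
  if (x$repair_count > 0) {
    cat(sprintf("  %d bootstrap correlation matrices repaired by eigenvalue clipping\n",
                x$repair_count))
  }
  invisible(x)
}

#' Edge-list view of an estimated network
#'
#' @param network An `estimated_network`.
#' @return Data frame with one row per node pair: `node1`, `node2`,
#'   `weight`, `ci_lower`, `ci_upper`, `included`.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "estimated_network"))
  idx <- edge_pairs(length(network$node_labels))
  labs <- network$node_labels
  data.frame(
    node1 = labs[idx[, 1]], node2 = labs[idx[, 2]],
    weight = network$weights[idx],
    ci_lower = network$ci_lower[idx],
    ci_upper = network$ci_upper[idx],
    included = network$included[idx],
    stringsAsFactors = FALSE
  )
}
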
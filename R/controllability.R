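# Average and modal controllability under discrete-time linear dynamics
# x(t+1) = A x(t) + B u(t), with the adjacency stabilized by spectral
# normalization.

#' Normalize an adjacency matrix for controllability analysis
#'
#' Divides the symmetric weight matrix by c = 1 + |lambda_max|, where
#' lambda_max is the largest-magnitude eigenvalue, so the result is Schur
#' stable (spectral radius strictly below 1).
#'
#' @param weights Symmetric matrix with zero diagonal (signed selected
#'   network weights).
#' @return Normalized matrix; attributes `"scaling"` (the constant c) and
#'   `"spectral_radius"` record the normalization.
#' @export
normalize_adjacency <- function(weights) {
  check_symmetric(weights, "adjacency matrix")
  if (any(abs(diag(weights)) > 1e-12)) {
    stop("adjacency matrix must have a zero diagonal", call. = FALSE)
  }
  lam <- eigen(weights, symmetric = TRUE, only.values = TRUE)$values
  cc <- 1 + max(abs(lam))
  a <- weights / cc
  attr(a, "scaling") <- cc
  attr(a, "spectral_radius") <- max(abs(lam)) / cc
  a
}

# Eigendecomposition with the stability check shared by both metrics.
ctrl_eigen <- function(a_norm) {
  check_symmetric(a_norm, "normalized adjacency")
  e <- eigen(a_norm, symmetric = TRUE)
  if (max(abs(e$values)) >= 1) {
    stop("normalized adjacency must have spectral radius < 1", call. = FALSE)
  }
  e
}

#' Average controllability of each node
#'
#' For input at node i (B = e_i), the infinite-horizon controllability
#' Gramian solves the discrete Lyapunov equation W = A W A' + B B'; average
#' controllability is trace(W). For symmetric A the solve has the closed
#' form trace(W_i) = sum_j v_ij^2 / (1 - lambda_j^2) over the
#' eigendecomposition A = V diag(lambda) V'. Values are always >= 1 (the
#' tau = 0 Gramian term contributes e_i' e_i = 1).
#'
#' @param a_norm Symmetric matrix with spectral radius < 1 (see
#'   [normalize_adjacency()]).
#' @return Named numeric vector of per-node Gramian traces.
#' @export
average_controllability <- function(a_norm) {
  e <- ctrl_eigen(a_norm)
  out <- as.vector(e$vectors^2 %*% (1 / (1 - e$values^2)))
  stats::setNames(out, colnames(a_norm))
}

#' Modal controllability of each node
#'
#' phi_i = sum_j (1 - lambda_j^2) v_ij^2 over the orthonormal
#' eigendecomposition of the (symmetric) normalized adjacency: nodes that
#' load on fast-decaying modes (small |lambda_j|) score high, indicating
#' capacity to push the system toward rare states.
#'
#' @inheritParams average_controllability
#' @return Named numeric vector.
#' @export
modal_controllability <- function(a_norm) {
  e <- ctrl_eigen(a_norm)
  out <- as.vector(e$vectors^2 %*% (1 - e$values^2))
  stats::setNames(out, colnames(a_norm))
}

#' Controllability profile of an estimated network
#'
#' Normalizes the signed selected weight matrix ([normalize_adjacency()])
#' and computes average and modal controllability of every node.
#'
#' @param network An `estimated_network` or signed symmetric weight matrix
#'   with zero diagonal.
#' @return Data frame with `node`, `avg_ctrl`, `modal_ctrl`; attributes
#'   `"scaling"` and `"spectral_radius"` record the normalization.
#' @export
controllability_scores <- function(network) {
  w <- if (inherits(network, "estimated_network")) {
    selected_weights(network)
  } else {
    as.matrix(network)
  }
  a <- normalize_adjacency(w)
  out <- data.frame(
    node = colnames(w),
    avg_ctrl = unname(average_controllability(a)),
    modal_ctrl = unname(modal_controllability(a)),
    stringsAsFactors = FALSE
  )
  attr(out, "scaling") <- attr(a, "scaling")
  attr(out, "spectral_radius") <- attr(a, "spectral_radius")
  out
}
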
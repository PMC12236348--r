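# Node predictability: variance of each node explained by its selected
# neighbors.

#' Node predictability
#'
#' For each node, regresses its rank-transformed values on the
#' rank-transformed values of its included neighbors (least squares) and
#' reports R-squared. The rank transform keeps the measure consistent with
#' the Spearman-based network; a node with no included edges has R-squared
#' 0 by convention. Constant neighbor columns are dropped and recorded.
#'
#' @param table Subscale data the network was estimated from.
#' @param network The `estimated_network` (supplies the neighbor sets).
#' @return Data frame with `node`, `r_squared`, `n_neighbors` (neighbors
#'   actually used); attribute `"dropped"` lists constant neighbors
#'   removed from any design.
#' @export
node_predictability <- function(table, network) {
  stopifnot(inherits(network, "estimated_network"))
  x <- subscale_matrix(table, network$node_labels)
  x <- x[complete.cases(x), , drop = FALSE]
  r <- rank_columns(x)
  p <- ncol(r)
  dropped <- character()

  r2 <- vapply(seq_len(p), function(i) {
    nb <- which(network$included[i, ])
    if (!length(nb)) return(0)
    keep <- nb[apply(r[, nb, drop = FALSE], 2L, sd) > 0]
    if (length(keep) < length(nb)) {
      dropped <<- c(dropped, network$node_labels[setdiff(nb, keep)])
    }
    if (!length(keep)) return(0)
    y <- r[, i]
    fit <- lm.fit(cbind(1, r[, keep, drop = FALSE]), y)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) return(0)
    max(0, min(1, 1 - ss_res / ss_tot))
  }, numeric(1))

  out <- data.frame(
    node = network$node_labels,
    r_squared = r2,
    n_neighbors = rowSums(network$included),
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- unique(dropped)
  out
}
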
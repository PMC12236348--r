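# Shared internal helpers.

# Symmetry check with a numerical tolerance; many operations require it.
check_symmetric <- function(m, what = "matrix", tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic per-stage seed derived from a master seed; keeps every
# stage independently re-runnable with identical randomness.
stage_seed <- function(master_seed, stage) {
  (as.integer(master_seed) %% 1000000L) + 1009L * as.integer(stage)
}

# Extract the numeric observation matrix (nodes as columns) from a
# subscale table, dropping identifier/total columns.
subscale_matrix <- function(table, labels = node_labels()) {
  if (is.matrix(table)) {
    if (is.null(colnames(table))) colnames(table) <- labels
    return(table[, labels, drop = FALSE])
  }
  missing_cols <- setdiff(labels, names(table))
  if (length(missing_cols)) {
    stop("subscale table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as.matrix(table[, labels, drop = FALSE])
}

# Column-wise midranks (average ranks for ties), the rank transform behind
# every Spearman-based quantity in the package.
rank_columns <- function(x) {
  apply(x, 2L, rank, ties.method = "average")
}

# Upper-triangle index pairs of a p x p matrix, in column-major order.
edge_pairs <- function(p) {
  which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
}
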
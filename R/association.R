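# Bivariate Spearman associations.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average ranks are assigned to ties, rho is the Pearson correlation of
#' the ranks, and the two-sided p-value uses the t approximation with
#' n - 2 degrees of freedom (appropriate at the sample sizes this package
#' targets; heavily tied Likert sums make exact null distributions
#' impractical anyway).
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value
#'   are dropped.
#' @param labels Optional length-2 character vector naming the pair.
#' @return A `correlation_result`: list with `var1`, `var2`, `rho`, `p`,
#'   `n`.
#' @export
spearman_rho <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector",
         call. = FALSE)
  }
  rho <- cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(var1 = labels[1], var2 = labels[2],
                 rho = rho, p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho(%s, %s) = %.3f, p = %.3g, n = %d\n",
              x$var1, x$var2, x$rho, x$p, x$n))
  invisible(x)
}

#' Pairwise Spearman correlation matrix
#'
#' Computes all pairwise Spearman correlations over the numeric columns of
#' a table with pairwise-complete observations.
#'
#' @param table Data frame or matrix; non-numeric columns (for example
#'   `participant_id`) are dropped.
#' @return A `correlation_matrix`: list of symmetric matrices `rho`
#'   (unit diagonal), `p` and `n`.
#' @export
correlation_matrix <- function(table) {
  df <- as.data.frame(table)
  df <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(df) < 2L) stop("need at least 2 numeric columns", call. = FALSE)
  p <- ncol(df)
  labs <- names(df)
  rho <- diag(p); pval <- matrix(NA_real_, p, p); nmat <- matrix(NA_real_, p, p)
  dimnames(rho) <- dimnames(pval) <- dimnames(nmat) <- list(labs, labs)
  diag(pval) <- 0
  diag(nmat) <- colSums(!is.na(df))
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      r <- spearman_rho(df[[i]], df[[j]], labels = labs[c(i, j)])
      rho[i, j] <- rho[j, i] <- r$rho
      pval[i, j] <- pval[j, i] <- r$p
      nmat[i, j] <- nmat[j, i] <- r$n
    }
  }
  structure(list(rho = rho, p = pval, n = nmat),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("Spearman correlation matrix (", ncol(x$rho), " variables)\n", sep = "")
  print(round(x$rho, digits))
  invisible(x)
}

#' Long-format view of a correlation matrix
#'
#' @param cm A `correlation_matrix`.
#' @return Data frame with `var1`, `var2`, `rho`, `p`, `n`, one row per
#'   unordered variable pair.
#' @export
correlation_long <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  idx <- edge_pairs(ncol(cm$rho))
  labs <- colnames(cm$rho)
  data.frame(
    var1 = labs[idx[, 1]], var2 = labs[idx[, 2]],
    rho = cm$rho[idx], p = cm$p[idx], n = cm$n[idx],
    stringsAsFactors = FALSE
  )
}
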
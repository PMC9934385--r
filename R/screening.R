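## Two-stage gene screening used to build a regression design from an
## expression matrix: keep the k most variable genes, then the k genes most
## correlated (in absolute value) with a target transcript.

#' Variance screen
#'
#' Retains the `k` genes (columns) of largest sample variance, ties broken
#' by original column order; sample order is preserved.  Variances use the
#' unbiased `n - 1` denominator.
#'
#' @param expr numeric matrix, samples in rows and genes in columns
#'   (column names are the gene identifiers).
#' @param k number of genes to keep, `1 <= k <= ncol(expr)`.
#' @return the screened expression matrix.
#' @export
variance_screen <- function(expr, k) {
  expr <- as.matrix(expr)
  if (anyNA(expr)) stop("missing values are not supported")
  G <- ncol(expr)
  if (k < 1 || k > G) stop("'k' must be between 1 and ", G)
  v <- apply(expr, 2L, var)
  keep <- sort(order(-v, seq_len(G))[seq_len(k)])
  expr[, keep, drop = FALSE]
}

#' Marginal-correlation screen
#'
#' Retains the `k` genes with the largest absolute Pearson correlation with
#' a target vector (e.g. the expression of a disease gene), ties broken by
#' original column order.  Zero-variance genes get correlation 0, with a
#' warning.
#'
#' @inheritParams variance_screen
#' @param target numeric vector of length `nrow(expr)` with positive
#'   variance.
#' @return the screened expression matrix, original column order preserved
#'   among the retained genes.
#' @export
correlation_screen <- function(expr, target, k) {
  expr <- as.matrix(expr)
  if (anyNA(expr) || anyNA(target)) stop("missing values are not supported")
  if (length(target) != nrow(expr))
    stop("length(target) must equal nrow(expr)")
  if (var(target) <= 0) stop("'target' has zero variance")
  G <- ncol(expr)
  if (k < 1 || k > G) stop("'k' must be between 1 and ", G)
  v <- apply(expr, 2L, var)
  r <- numeric(G)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s); correlation set to 0")
    r[v > 0] <- abs(cor(expr[, v > 0, drop = FALSE], target))
  } else {
    r <- abs(drop(cor(expr, target)))
  }
  keep <- sort(order(-r, seq_len(G))[seq_len(k)])
  expr[, keep, drop = FALSE]
}
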
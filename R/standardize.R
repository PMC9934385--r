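#' Standardize a regression problem
#'
#' Centers each predictor column and scales it so that
#' \eqn{\sum_i x_{ij}^2 / n = 1}, and centers the response.  All solvers in
#' the package operate on this representation; fitted objects carry the
#' scaling metadata so coefficients and predictions can be mapped back to
#' the original variables.
#'
#' @param X numeric matrix or data frame of predictors, `n x p`.
#' @param y numeric response vector of length `n`.
#' @return an object of class `"lqsso_data"`: a list with the standardized
#'   `X`, centered `y`, dimensions `n`, `p`, and `scaling` (per-column
#'   `center` and `scale`, plus `y_mean`).
#' @examples
#' d <- standardize_xy(matrix(rnorm(40), 10, 4), rnorm(10))
#' colMeans(d$X)            # ~ 0
#' colMeans(d$X^2)          # ~ 1
#' @export
standardize_xy <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least two samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  scale <- sqrt(colMeans(Xc^2))
  bad <- which(scale < 1e-12)
  if (length(bad)) {
    nm <- if (!is.null(colnames(X))) colnames(X)[bad] else as.character(bad)
    stop("constant column(s): ", paste(nm, collapse = ", "))
  }
  Xs <- sweep(Xc, 2L, scale, "/")
  y_mean <- mean(y)
  structure(list(X = Xs, y = y - y_mean, n = n, p = p,
                 scaling = list(center = center, scale = scale,
                                y_mean = y_mean)),
            class = "lqsso_data")
}

#' @export
print.lqsso_data <- function(x, ...) {
  cat("Standardized regression data: n =", x$n, ", p =", x$p, "\n")
  invisible(x)
}
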
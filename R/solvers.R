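## Coordinate-descent solvers for lasso, weighted lasso, adaptive lasso and
## lqsso.  All objectives are on the raw residual-sum-of-squares scale,
##   RSS(beta) + lambda * sum_j w_j^q |beta_j|,
## with no 1/(2n) factor.  Users of per-observation path solvers can convert
## with lambda_objective().

## Internal: solve the weighted-L1 path on an arbitrary design.
## Returns p x nlam coefficient matrix plus diagnostics.
cd_path <- function(X, y, lambda, penalty_factor = rep(1, ncol(X)),
                    tol = 1e-8, max_iter = 1e5L) {
  stopifnot(all(lambda >= 0), all(penalty_factor > 0))
  ord <- order(lambda, decreasing = TRUE)
  res <- .cd_lasso_path(X, y, as.numeric(lambda[ord]),
                        as.numeric(penalty_factor), tol, as.integer(max_iter))
  inv <- order(ord)
  list(beta = res$beta[, inv, drop = FALSE],
       iters = res$iters[inv], converged = res$converged[inv])
}

## Internal: assemble a fit object from a standardized-scale solution.
new_fit <- function(data, beta, lambda, weights, q, method,
                    tau = NA_real_, gamma = NA_real_,
                    init_source = NA_character_, n_iter = NA_integer_,
                    converged = TRUE) {
  beta <- as.numeric(beta)
  sc <- data$scaling
  beta_orig <- beta / sc$scale
  intercept <- sc$y_mean - sum(sc$center * beta_orig)
  rss <- sum((data$y - data$X %*% beta)^2)
  spec <- penalty_spec(tau = tau, weights = weights, lambda = lambda, q = q)
  structure(list(beta = beta, beta_original = beta_orig,
                 intercept = intercept,
                 lambda = lambda, tau = tau, gamma = gamma, q = q,
                 weights = weights, method = method,
                 init_source = init_source,
                 active_set = which(beta != 0),
                 objective = rss + penalty_value(beta, spec),
                 rss = rss, n_iter = n_iter, converged = converged),
            class = "lqsso_fit")
}

#' Lasso by coordinate descent
#'
#' Minimizes the L1-penalized residual sum of squares
#' \deqn{\sum_i (y_i - \sum_j \beta_j x_{ij})^2 + \lambda \sum_j |\beta_j|}
#' by cyclic coordinate descent with exact soft-thresholding updates.  Note
#' the objective carries no \eqn{1/(2n)} factor; see [lambda_objective()]
#' for conversion from per-observation penalty scales.
#'
#' @param data an [standardize_xy()] object.
#' @param lambda single penalty strength \eqn{\ge 0} on the objective scale.
#' @param tol convergence tolerance on the largest coefficient change per
#'   sweep (measured on the standardized-column scale).
#' @param max_iter maximum number of coordinate sweeps.
#' @return an object of class `"lqsso_fit"` with elements `beta`
#'   (standardized scale), `beta_original` and `intercept` (original
#'   scale), `active_set`, `objective`, `n_iter` and `converged`.
#'   Non-convergence is flagged, never silent.
#' @seealso [weighted_lasso()], [lqsso()], [adaptive_lasso()]
#' @export
lasso_cd <- function(data, lambda, tol = 1e-8, max_iter = 1e5L) {
  stopifnot(inherits(data, "lqsso_data"), length(lambda) == 1L, lambda >= 0)
  sol <- cd_path(data$X, data$y, lambda, rep(1, data$p), tol, max_iter)
  if (!sol$converged[1L])
    warning("coordinate descent did not converge in ", max_iter, " sweeps")
  new_fit(data, sol$beta[, 1L], lambda, weights = rep(1, data$p), q = 1,
          method = "lasso", n_iter = sol$iters[1L],
          converged = sol$converged[1L])
}

#' Weighted lasso via column rescaling
#'
#' Solves \eqn{\min_\beta \sum_i (y_i - \sum_j \beta_j x_{ij})^2 +
#' \lambda \sum_j w_j^q |\beta_j|} by the standard reduction to a plain
#' lasso: rescale each column as \eqn{x_j^* = x_j / w_j^q}, solve the lasso
#' on the rescaled design, and divide the solution coordinatewise by
#' \eqn{w_j^q}.
#'
#' @inheritParams lasso_cd
#' @param weights strictly positive weight vector of length `p` (clamp
#'   nonpositive weights first, e.g. with [lqsso_weights()]).
#' @param q weight exponent; default 1.
#' @return an `"lqsso_fit"` object.
#' @export
weighted_lasso <- function(data, lambda, weights, q = 1,
                           tol = 1e-8, max_iter = 1e5L) {
  stopifnot(inherits(data, "lqsso_data"), length(lambda) == 1L, lambda >= 0)
  if (length(weights) != data$p) stop("length(weights) must equal p")
  if (any(weights <= 0)) stop("all weights must be strictly positive")
  wq <- weights^q
  Xs <- sweep(data$X, 2L, wq, "/")
  sol <- cd_path(Xs, data$y, lambda, rep(1, data$p), tol, max_iter)
  if (!sol$converged[1L])
    warning("coordinate descent did not converge in ", max_iter, " sweeps")
  new_fit(data, sol$beta[, 1L] / wq, lambda, weights = weights, q = q,
          method = "weighted_lasso", n_iter = sol$iters[1L],
          converged = sol$converged[1L])
}

#' Least quantile shrinkage and selection operator
#'
#' Fits the lqsso estimator: a weighted lasso whose weight for coefficient
#' \eqn{j} is \eqn{\tau} if the initial estimate of \eqn{\beta_j} is
#' positive and \eqn{1 - \tau} otherwise, i.e. the quantile check function
#' evaluated at the sign of the initial fit.  At \eqn{\tau = 0.5} all
#' weights equal \eqn{1/2} and the fit coincides with the lasso at
#' \eqn{\lambda/2}.
#'
#' @inheritParams weighted_lasso
#' @param tau quantile level in \eqn{[0, 1]}.
#' @param init initial estimates: an object from [ols_init()] or
#'   [ridge_init()], a plain numeric vector, or `NULL` to choose
#'   automatically (OLS when `p < n`, ridge otherwise).
#' @param eps lower clamp for the penalty weights.
#' @return an `"lqsso_fit"` object recording `tau` and the initial-estimate
#'   source.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 40, 5)
#' y <- drop(X %*% c(2, -1, 0, 0, 1)) + rnorm(40)
#' d <- standardize_xy(X, y)
#' f <- lqsso(d, lambda = 20, tau = 0.7)
#' f$active_set
#' @export
lqsso <- function(data, lambda, tau, init = NULL, q = 1, eps = 1e-8,
                  tol = 1e-8, max_iter = 1e5L) {
  stopifnot(inherits(data, "lqsso_data"), tau >= 0, tau <= 1)
  init <- resolve_init(data, init)
  w <- lqsso_weights(init$beta, tau, eps = eps)
  fit <- weighted_lasso(data, lambda, w, q = q, tol = tol,
                        max_iter = max_iter)
  fit$method <- "lqsso"
  fit$tau <- tau
  fit$init_source <- init$source
  fit
}

#' Adaptive lasso
#'
#' Weighted lasso with weights \eqn{\hat w_j = 1/|\hat\beta_{j,init}|^\gamma}
#' from an initial OLS or ridge fit.
#'
#' @inheritParams lqsso
#' @param gamma positive weight exponent.
#' @return an `"lqsso_fit"` object recording `gamma` and the
#'   initial-estimate source.
#' @export
adaptive_lasso <- function(data, lambda, gamma, init = NULL, eps = 1e-8,
                           tol = 1e-8, max_iter = 1e5L) {
  stopifnot(inherits(data, "lqsso_data"), gamma > 0)
  init <- resolve_init(data, init)
  w <- adaptive_weights(init$beta, gamma, eps = eps)
  fit <- weighted_lasso(data, lambda, w, q = 1, tol = tol,
                        max_iter = max_iter)
  fit$method <- "alasso"
  fit$gamma <- gamma
  fit$init_source <- init$source
  fit
}

resolve_init <- function(data, init) {
  if (is.null(init)) {
    if (data$p < data$n) ols_init(data) else ridge_init(data)
  } else if (inherits(init, "lqsso_init")) {
    if (length(init$beta) != data$p) stop("initial estimates have wrong length")
    init
  } else {
    if (length(init) != data$p) stop("initial estimates have wrong length")
    if (anyNA(init) || any(!is.finite(init)))
      stop("initial estimates must be finite")
    structure(list(beta = as.numeric(init), source = "user"),
              class = "lqsso_init")
  }
}

#' Ordinary least squares initial estimates
#'
#' \eqn{\hat\beta = (X^\top X)^{-1} X^\top y} on the standardized scale,
#' used to seed the lqsso and adaptive-lasso penalty weights.  Requires
#' `p < n` and a nonsingular Gram matrix; for `p >= n` use [ridge_init()].
#'
#' @param data an [standardize_xy()] object.
#' @return an object of class `"lqsso_init"` with elements `beta` and
#'   `source`.
#' @export
ols_init <- function(data) {
  stopifnot(inherits(data, "lqsso_data"))
  if (data$p >= data$n)
    stop("p >= n: OLS initial estimates are unavailable; use ridge_init()")
  G <- crossprod(data$X)
  beta <- tryCatch(solve(G, crossprod(data$X, data$y)),
                   error = function(e)
                     stop("X'X is singular; use ridge_init()", call. = FALSE))
  structure(list(beta = drop(beta), source = "ols"), class = "lqsso_init")
}

#' Ridge initial estimates
#'
#' \eqn{\hat\beta = (X^\top X + \lambda_r I)^{-1} X^\top y}, the standard
#' initializer for penalty weights when `p >= n`.  When `ridge_lambda` is
#' not supplied it is selected by closed-form leave-one-out cross-validation
#' over a log-spaced grid, computed from one singular value decomposition.
#'
#' @param data an [standardize_xy()] object.
#' @param ridge_lambda positive ridge penalty, or `NULL` to select by
#'   internal cross-validation.
#' @return an object of class `"lqsso_init"`; the selected penalty is
#'   stored as `ridge_lambda`.
#' @export
ridge_init <- function(data, ridge_lambda = NULL) {
  stopifnot(inherits(data, "lqsso_data"))
  X <- data$X; y <- data$y
  sv <- svd(X)
  d <- sv$d
  uty <- drop(crossprod(sv$u, y))
  if (is.null(ridge_lambda)) {
    grid <- 10^seq(-4, 4, length.out = 45)
    best <- Inf
    for (lam in grid) {
      f <- d^2 / (d^2 + lam)
      h <- rowSums(sweep(sv$u, 2L, f, "*") * sv$u)  # leverage under ridge
      res <- y - drop(sv$u %*% (f * uty))
      cvv <- mean((res / pmax(1 - h, 1e-12))^2)
      if (cvv < best) { best <- cvv; ridge_lambda <- lam }
    }
  }
  if (!is.numeric(ridge_lambda) || ridge_lambda <= 0)
    stop("'ridge_lambda' must be positive")
  beta <- drop(sv$v %*% ((d / (d^2 + ridge_lambda)) * uty))
  structure(list(beta = beta, source = "ridge", ridge_lambda = ridge_lambda),
            class = "lqsso_init")
}

#' Convert a per-observation penalty to the objective scale
#'
#' The package's objective is `RSS + lambda * penalty`.  Path solvers such
#' as glmnet use `RSS/(2n) + lambda * penalty`; a value `lambda_obs` on that
#' scale corresponds to `2 * n * lambda_obs` here.
#'
#' @param lambda penalty on the per-observation scale.
#' @param n number of samples.
#' @return the equivalent penalty on the objective scale.
#' @export
lambda_objective <- function(lambda, n) 2 * n * lambda

#' Karush-Kuhn-Tucker solution verification
#'
#' Checks the first-order optimality conditions of the weighted-L1
#' objective at a fitted solution: for active coordinates
#' \eqn{2 x_j^\top (y - X\hat\beta) = \lambda w_j^q \,\mathrm{sign}(\hat\beta_j)}
#' must hold, and for inactive coordinates
#' \eqn{|2 x_j^\top (y - X\hat\beta)| \le \lambda w_j^q}.  Used as an
#' independent certificate that a returned fit is the global minimizer.
#'
#' @param data the [standardize_xy()] object the fit was computed on.
#' @param fit an `"lqsso_fit"` object.
#' @param tol absolute tolerance for both condition groups.
#' @return a list with `ok`, the worst violation per group
#'   (`worst_active`, `worst_inactive`) and a per-coordinate table.
#' @export
kkt_check <- function(data, fit, tol = 1e-6) {
  stopifnot(inherits(data, "lqsso_data"), inherits(fit, "lqsso_fit"))
  g <- drop(2 * crossprod(data$X, data$y - data$X %*% fit$beta))
  bound <- fit$lambda * fit$weights^fit$q
  active <- fit$beta != 0
  viol <- numeric(data$p)
  viol[active] <- abs(g[active] - bound[active] * sign(fit$beta[active]))
  viol[!active] <- pmax(abs(g[!active]) - bound[!active], 0)
  worst_a <- if (any(active)) max(viol[active]) else 0
  worst_i <- if (any(!active)) max(viol[!active]) else 0
  list(ok = worst_a <= tol && worst_i <= tol,
       worst_active = worst_a, worst_inactive = worst_i,
       table = data.frame(coordinate = seq_len(data$p), active = active,
                          gradient = g, bound = bound, violation = viol))
}

#' @export
print.lqsso_fit <- function(x, ...) {
  cat(sprintf("%s fit: lambda = %g", x$method, x$lambda))
  if (!is.na(x$tau)) cat(sprintf(", tau = %g", x$tau))
  if (!is.na(x$gamma)) cat(sprintf(", gamma = %g", x$gamma))
  cat(sprintf("\n  %d active of %d coefficients; objective = %g%s\n",
              length(x$active_set), length(x$beta), x$objective,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

#' Predict from a fitted penalized regression
#'
#' @param object an `"lqsso_fit"` object.
#' @param newdata matrix of predictors on the original (unstandardized)
#'   scale.
#' @param ... unused.
#' @return vector of predictions.
#' @export
predict.lqsso_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$beta_original) + object$intercept
}

#' Extract coefficients
#'
#' @param object an `"lqsso_fit"` object.
#' @param scale `"original"` (default, includes the intercept as first
#'   element) or `"standardized"`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.lqsso_fit <- function(object, scale = c("original", "standardized"),
                           ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") return(object$beta)
  c("(Intercept)" = object$intercept, object$beta_original)
}
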
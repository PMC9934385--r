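#' Quantile check function
#'
#' The asymmetric absolute loss of quantile regression,
#' \deqn{\rho_\tau(u) = [\tau - I(u \le 0)]\,u,}
#' which charges \eqn{\tau |u|} for positive \eqn{u} and
#' \eqn{(1-\tau)|u|} otherwise.  It is the building block of the lqsso
#' penalty: evaluated at the sign of an initial coefficient estimate it
#' yields the penalty weight for that coordinate.
#'
#' @param u numeric vector; must be finite.
#' @param tau quantile level in \eqn{[0, 1]}.
#' @return `rho_tau(u)`, a nonnegative numeric vector the length of `u`.
#' @examples
#' check_function(c(-1, 0, 1), tau = 0.8)  # 0.2, 0, 0.8
#' @export
check_function <- function(u, tau) {
  if (!is.numeric(u) || anyNA(u) || any(!is.finite(u)))
    stop("'u' must be finite numeric")
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0, tau <= 1)
  (tau - (u <= 0)) * u
}

#' Lqsso penalty weights from initial estimates
#'
#' Each coordinate receives weight \eqn{\tau} if its initial estimate is
#' positive and \eqn{1 - \tau} otherwise (a zero initial estimate falls in
#' the non-positive branch).  Weights therefore depend only on the signs of
#' the initial fit and always lie in \eqn{[\min(\tau,1-\tau),
#' \max(\tau,1-\tau)]} before clamping.  At the endpoints \eqn{\tau \in
#' \{0,1\}} one sign group would receive weight zero, which breaks the
#' column rescaling used by the solver, so weights are clamped below at
#' `eps` (those coordinates become effectively unpenalized).
#'
#' @param beta_init numeric vector of initial coefficient estimates (OLS or
#'   ridge), or an object returned by [ols_init()]/[ridge_init()].
#' @param tau quantile level in \eqn{[0, 1]}.
#' @param eps lower clamp for the weights; default `1e-8`.
#' @return numeric weight vector, same length as `beta_init`.
#' @examples
#' lqsso_weights(c(2, -3, 0), tau = 0.8)  # 0.8, 0.2, 0.2
#' @export
lqsso_weights <- function(beta_init, tau, eps = 1e-8) {
  if (inherits(beta_init, "lqsso_init")) beta_init <- beta_init$beta
  if (!is.numeric(beta_init) || anyNA(beta_init) || any(!is.finite(beta_init)))
    stop("'beta_init' must be finite numeric")
  stopifnot(tau >= 0, tau <= 1, eps > 0)
  pmax(ifelse(beta_init > 0, tau, 1 - tau), eps)
}

#' Adaptive-lasso weights from initial estimates
#'
#' The classical data-driven weights \eqn{\hat w_j = 1/|\hat\beta_j|^\gamma}.
#' Coordinates whose initial estimate is (numerically) zero get their
#' magnitude clamped below at `eps`, capping the weight at
#' \eqn{(1/\mathrm{eps})^\gamma}.
#'
#' @inheritParams lqsso_weights
#' @param gamma positive weight exponent.
#' @return numeric weight vector.
#' @export
adaptive_weights <- function(beta_init, gamma, eps = 1e-8) {
  if (inherits(beta_init, "lqsso_init")) beta_init <- beta_init$beta
  if (!is.numeric(beta_init) || anyNA(beta_init) || any(!is.finite(beta_init)))
    stop("'beta_init' must be finite numeric")
  stopifnot(gamma > 0, eps > 0)
  if (all(beta_init == 0))
    stop("all initial estimates are zero; adaptive weights undefined")
  1 / pmax(abs(beta_init), eps)^gamma
}

#' Penalty specification
#'
#' Bundles the quantile level, weight exponent, realized weight vector and
#' penalty strength of a weighted-L1 penalty
#' \eqn{\lambda \sum_j w_j^q |\beta_j|}.
#'
#' @param tau quantile level in \eqn{[0,1]} (recorded; may be `NA` for
#'   penalties not derived from the check function).
#' @param weights nonnegative weight vector, one entry per coefficient.
#' @param lambda penalty strength \eqn{\lambda \ge 0} on the objective scale
#'   (residual sum of squares plus penalty).
#' @param q weight exponent; default 1.
#' @return an object of class `"penalty_spec"`.
#' @export
penalty_spec <- function(tau = NA_real_, weights, lambda, q = 1) {
  stopifnot(is.numeric(weights), all(is.finite(weights)), all(weights >= 0))
  if (!is.na(tau)) stopifnot(tau >= 0, tau <= 1)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("'lambda' must be a single nonnegative number")
  structure(list(tau = tau, q = q, weights = as.numeric(weights),
                 lambda = lambda),
            class = "penalty_spec")
}

#' Weighted-L1 penalty value
#'
#' Evaluates \eqn{\lambda \sum_j w_j^q |\beta_j|} for a coefficient vector.
#'
#' @param beta coefficient vector.
#' @param spec a [penalty_spec()] whose weight vector matches `beta` in
#'   length.
#' @return a single nonnegative number; zero iff `beta = 0` or
#'   `lambda = 0`.
#' @export
penalty_value <- function(beta, spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (length(beta) != length(spec$weights))
    stop("length(beta) does not match length(spec$weights)")
  spec$lambda * sum(spec$weights^spec$q * abs(beta))
}
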